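# Configuration parsing/validation, named fixture geometries, and result
# serialization (CSV spectra + JSON metadata).

.ring_keys <- c("N", "R_over_lambda", "d_over_lambda", "z_over_lambda",
                "delta_rad", "theta_rad", "phi_rad", "detuning_Gamma0",
                "label")
.top_keys <- c("rings", "experiment", "output_dir", "tolerances", "seed")

ring_from_config <- function(rc, where = "ring") {
  # YAML 1.1 resolves a bare key `N` to boolean FALSE; undo that
  names(rc)[names(rc) == "FALSE"] <- "N"
  unknown <- setdiff(names(rc), .ring_keys)
  if (length(unknown) > 0)
    stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(rc$N)) stop(where, ": key 'N' is required")
  has_R <- !is.null(rc$R_over_lambda)
  has_d <- !is.null(rc$d_over_lambda)
  if (has_R && has_d)
    stop(where, ": give either R_over_lambda or d_over_lambda, not both")
  if (!has_R && !has_d)
    stop(where, ": one of R_over_lambda, d_over_lambda is required")
  ring_spec(N = rc$N,
            R = rc$R_over_lambda, d = rc$d_over_lambda,
            z = rc$z_over_lambda %||% 0,
            delta = rc$delta_rad %||% 0,
            theta = rc$theta_rad %||% 0,
            phi = rc$phi_rad %||% 0,
            detuning = rc$detuning_Gamma0 %||% 0,
            label = rc$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with a \code{rings} list (keys:
#' \code{N}, one of \code{R_over_lambda}/\code{d_over_lambda},
#' \code{z_over_lambda}, \code{delta_rad}, \code{theta_rad},
#' \code{phi_rad}, \code{detuning_Gamma0}, \code{label}) plus optional
#' \code{experiment}, \code{output_dir}, \code{tolerances} and \code{seed}.
#' Unknown keys are rejected, all keys carry explicit unit suffixes, and
#' defaults (delta = 0, detuning = 0, z = 0) are filled in.
#'
#' @param path file path.
#' @return list of class \code{run_config} with \code{$specs} (list of
#'   \code{ring_spec}) and the remaining fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .top_keys)
  if (length(unknown) > 0)
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$rings) || length(raw$rings) == 0)
    stop("config must define at least one ring")
  specs <- lapply(seq_along(raw$rings), function(k)
    ring_from_config(raw$rings[[k]], where = paste0("rings[", k, "]")))
  structure(list(specs = specs,
                 experiment = raw$experiment,
                 output_dir = raw$output_dir,
                 tolerances = raw$tolerances,
                 seed = raw$seed),
            class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' Inverse of \code{\link{load_config}} up to default filling:
#' \code{load_config(write_config(cfg, f))} rebuilds identical ring specs.
#'
#' @param config a \code{run_config}.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  rings <- lapply(config$specs, function(s) {
    r <- list(N = s$N, R_over_lambda = s$R, z_over_lambda = s$z,
              delta_rad = s$delta, theta_rad = s$theta, phi_rad = s$phi,
              detuning_Gamma0 = s$detuning)
    if (!is.na(s$label)) r$label <- s$label
    r
  })
  out <- list(rings = rings)
  for (k in c("experiment", "output_dir", "tolerances", "seed"))
    if (!is.null(config[[k]])) out[[k]] <- config[[k]]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Named fixture geometries
#'
#' Pre-registered parameter sets for the package's standard study
#' configurations. Available names:
#' \describe{
#'   \item{large_ring}{single ring, N = 100, d = lambda/3 (quasi-chain).}
#'   \item{dicke_ring}{single ring, N = 20, d = 0.05 lambda (small-ring
#'     regime).}
#'   \item{stacked_pair}{two identical rings, N = 9, R = 0.05 lambda,
#'     Z = 0.5 R, delta = 0.}
#'   \item{scaling_pair}{double-ring scaling setup: d = lambda/3,
#'     Z = 0.009 lambda, transverse.}
#'   \item{field_pair}{two identical rings, N = 9, d = 0.1 lambda,
#'     Z = 0.2 lambda, tangential (field maps).}
#'   \item{rotated_pair_stacked}{two identical rings, N = 9,
#'     R = 0.05 lambda, Z = 0.1 R, transverse (rotation sweep).}
#'   \item{rotated_pair_coplanar}{two coplanar rings, N = 9, radii
#'     0.05 / 0.045 lambda, tangential (rotation sweep).}
#'   \item{lh2}{synthetic approximate LH2 motif (see
#'     \code{\link{lh2_params}}).}
#' }
#'
#' @param name fixture name.
#' @param polarization dipole orientation for the single/double-ring
#'   fixtures that support variants.
#' @return a \code{run_config}.
#' @export
fixture <- function(name, polarization = NULL) {
  pol <- function(default) polarization_angles(polarization %||% default)
  cfg <- switch(
    name,
    large_ring = {
      a <- pol("transverse")
      list(specs = list(ring_spec(N = 100, d = 1 / 3, theta = a["theta"],
                                  phi = a["phi"])))
    },
    dicke_ring = {
      a <- pol("transverse")
      list(specs = list(ring_spec(N = 20, d = 0.05, theta = a["theta"],
                                  phi = a["phi"])))
    },
    stacked_pair = {
      a <- pol("transverse")
      list(specs = list(
        ring_spec(N = 9, R = 0.05, z = 0, theta = a["theta"], phi = a["phi"]),
        ring_spec(N = 9, R = 0.05, z = 0.5 * 0.05, theta = a["theta"],
                  phi = a["phi"])))
    },
    scaling_pair = {
      a <- pol("transverse")
      list(specs = list(
        ring_spec(N = 9, d = 1 / 3, z = 0, theta = a["theta"], phi = a["phi"]),
        ring_spec(N = 9, d = 1 / 3, z = 0.009, theta = a["theta"],
                  phi = a["phi"])),
        experiment = "scaling")
    },
    field_pair = {
      a <- pol("tangential")
      list(specs = list(
        ring_spec(N = 9, d = 0.1, z = 0, theta = a["theta"], phi = a["phi"]),
        ring_spec(N = 9, d = 0.1, z = 0.2, theta = a["theta"],
                  phi = a["phi"])))
    },
    rotated_pair_stacked = {
      a <- pol("transverse")
      list(specs = list(
        ring_spec(N = 9, R = 0.05, z = 0, theta = a["theta"], phi = a["phi"]),
        ring_spec(N = 9, R = 0.05, z = 0.1 * 0.05, theta = a["theta"],
                  phi = a["phi"])))
    },
    rotated_pair_coplanar = {
      a <- pol("tangential")
      list(specs = list(
        ring_spec(N = 9, R = 0.05, z = 0, theta = a["theta"], phi = a["phi"]),
        ring_spec(N = 9, R = 0.045, z = 0, theta = a["theta"],
                  phi = a["phi"])))
    },
    lh2 = {
      params <- lh2_params()
      cn <- c("b850a", "b850b", "b800")
      list(specs = lapply(cn, function(nm) {
        p <- params[[nm]]
        ring_spec(N = params$N, R = p$R_nm / params$lambda_nm,
                  z = p$z_nm / params$lambda_nm, delta = p$offset_rad,
                  theta = p$theta_rad, phi = p$phi_rad,
                  detuning = p$detuning_Gamma0, label = nm)
      }))
    },
    stop("unknown fixture '", name, "'; available: ",
         paste(c("large_ring", "dicke_ring", "stacked_pair", "scaling_pair",
                 "field_pair", "rotated_pair_stacked",
                 "rotated_pair_coplanar", "lh2"), collapse = ", "))
  )
  structure(c(cfg, list(name = name)), class = "run_config")
}

#' Build the emitter array of a run configuration
#'
#' @param config a \code{run_config}.
#' @export
build_config <- function(config) build_stack(config$specs)

#' Write a mode spectrum to CSV (+ JSON metadata)
#'
#' @param spectrum a \code{mode_spectrum}.
#' @param path CSV output path; metadata is written alongside with extension
#'   \code{.json} when \code{meta} is given.
#' @param meta optional named list serialized as JSON sidecar.
#' @export
write_spectrum_csv <- function(spectrum, path, meta = NULL) {
  tab <- spectrum$modes
  if (!is.null(spectrum$populations))
    tab <- cbind(tab, as.data.frame(spectrum$populations))
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(meta)) {
    jpath <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
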