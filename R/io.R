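#' Run configuration
#'
#' A flat, serializable description of a model setup: the measured rates
#' (`beta_per_min`, `delta_per_min`), the calibration targets (`target_F`,
#' `target_phi`), the per-synapse slot counts, and optional explicit
#' `alpha_per_min` / `gamma_per_min` that override the calibration. Defaults
#' are the standard parameters: `beta = (43 s)^-1`, `delta = (14 min)^-1`,
#' `phi = 2.67`, `F = 0.9`.
#'
#' @param target_F target long-term filling fraction in (0, 1).
#' @param target_phi target relative pool size (> 0).
#' @param slots per-synapse slot counts.
#' @param beta_per_min unbinding rate, per minute.
#' @param delta_per_min internalization rate, per minute.
#' @param alpha_per_min optional explicit binding rate (overrides
#'   calibration; `gamma` is then set to reach `target_phi` with this alpha).
#' @param gamma_per_min optional explicit externalization rate.
#' @return an object of class `"run_config"`.
#' @export
#' @examples
#' cfg <- run_config(target_F = 0.5, slots = c(20, 40, 60, 80))
#' resolve_rates(cfg)
run_config <- function(target_F = 0.9, target_phi = 2.67,
                       slots = c(40, 60, 80),
                       beta_per_min = 60 / 43, delta_per_min = 1 / 14,
                       alpha_per_min = NULL, gamma_per_min = NULL) {
  if (!is.numeric(target_F) || target_F <= 0 || target_F >= 1)
    stop("'target_F' must lie strictly between 0 and 1")
  if (!is.numeric(target_phi) || target_phi <= 0)
    stop("'target_phi' must be > 0")
  if (!is.numeric(slots) || length(slots) < 1 || any(slots <= 0))
    stop("'slots' must be a vector of positive counts")
  if (beta_per_min <= 0 || delta_per_min <= 0)
    stop("'beta_per_min' and 'delta_per_min' must be > 0")
  structure(list(target_F = target_F, target_phi = target_phi,
                 slots = as.numeric(slots),
                 beta_per_min = beta_per_min, delta_per_min = delta_per_min,
                 alpha_per_min = alpha_per_min, gamma_per_min = gamma_per_min),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: N = %d synapses, S = %g slots\n",
              length(x$slots), sum(x$slots)))
  cat(sprintf("  targets: F = %g, phi = %g\n", x$target_F, x$target_phi))
  cat(sprintf("  beta = %g, delta = %g per min\n",
              x$beta_per_min, x$delta_per_min))
  if (!is.null(x$alpha_per_min)) cat(sprintf("  explicit alpha = %g\n", x$alpha_per_min))
  if (!is.null(x$gamma_per_min)) cat(sprintf("  explicit gamma = %g\n", x$gamma_per_min))
  invisible(x)
}

#' Resolve a configuration into kinetic rates
#'
#' If `alpha_per_min` and `gamma_per_min` are both given they are used as-is.
#' If only `alpha_per_min` is given, `gamma` is set so the relative pool size
#' hits `target_phi` with that fixed alpha (the filling fraction then becomes
#' `1 - beta/(alpha*phi*S)` rather than `target_F`). Otherwise both rates are
#' calibrated from `(target_F, target_phi, S)`.
#'
#' @param config a [run_config()].
#' @return a [rate_constants()] object.
#' @export
resolve_rates <- function(config) {
  S <- sum(config$slots)
  a <- config$alpha_per_min
  g <- config$gamma_per_min
  if (!is.null(a) && !is.null(g))
    return(rate_constants(a, config$beta_per_min, g, config$delta_per_min))
  if (!is.null(a)) {
    base <- rate_constants(a, config$beta_per_min, 1, config$delta_per_min)
    g <- as.numeric(gamma_for_pool_with_fixed_alpha(config$target_phi, S, base))
    return(rate_constants(a, config$beta_per_min, g, config$delta_per_min))
  }
  if (!is.null(g)) {
    a <- calibrate_alpha(config$target_F, config$target_phi, S,
                         config$beta_per_min)
    return(rate_constants(a, config$beta_per_min, g, config$delta_per_min))
  }
  calibrate_rates(config$target_F, config$target_phi, S,
                  beta = config$beta_per_min, delta = config$delta_per_min)
}

.config_keys <- c("target_F", "target_phi", "slots", "beta_per_min",
                  "delta_per_min", "alpha_per_min", "gamma_per_min")

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys take the standard defaults.
#'
#' @param path path to a JSON file.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to a JSON file
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a trajectory to a TSV file with a JSON metadata sidecar
#'
#' Columns are `time_min`, `w_1 ... w_N`, `p`, `W`, `R`, tab-separated with
#' C-locale decimal points. A sidecar `<path>.json` records the rates, the
#' Euler step and the event schedule.
#'
#' @param traj a `"trajectory"` from [integrate_model()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)))
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rates <- attr(traj, "rates")
  meta <- list(rates = rates[c("alpha", "beta", "gamma", "delta")],
               dt = attr(traj, "dt"),
               events = lapply(attr(traj, "events"), function(e)
                 e[c("time", "kind", "value", "targets")]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory()]
#'
#' The derived columns `W` and `R` are checked against the per-synapse
#' columns on load.
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  wcols <- grep("^w_", names(d))
  W <- rowSums(d[, wcols, drop = FALSE])
  if (length(wcols) && any(abs(W - d$W) > 1e-8 * pmax(1, abs(d$W))))
    stop("corrupt trajectory file: W does not match the sum of w columns")
  if (any(abs(d$W + d$p - d$R) > 1e-8 * pmax(1, abs(d$R))))
    stop("corrupt trajectory file: R does not match W + p")
  d
}
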