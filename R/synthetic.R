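#' Measurement noise model
#'
#' @param kind `"proportional_gaussian"` (sd proportional to the noiseless
#'   value) or `"additive_gaussian"` (constant sd).
#' @param sigma_rel relative sd (dimensionless fraction), used by the
#'   proportional model.
#' @param sigma_abs absolute sd in measurement units, used by the additive
#'   model.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("proportional_gaussian", "additive_gaussian"),
                        sigma_rel = 0.15, sigma_abs = 0) {
  kind <- match.arg(kind)
  if (sigma_rel < 0 || sigma_abs < 0) {
    stop("noise_model: sigma parameters must be >= 0", call. = FALSE)
  }
  structure(list(kind = kind, sigma_rel = sigma_rel, sigma_abs = sigma_abs),
            class = "noise_model")
}

noise_sd <- function(noise, clean) {
  if (noise$kind == "proportional_gaussian") noise$sigma_rel * clean
  else rep(noise$sigma_abs, length(clean))
}

#' Generate a synthetic two-arm mouse experiment
#'
#' Emulates the measurement structure of the CD/HFD tumor-implantation
#' experiment: two arms differing only in initial fat volume (and hence
#' initial estrogen, tied through the steady state `E0 = r*F0/mu`), tumor
#' volume measured in several independent replicate tumors at a few late
#' days, and a single fat-volume measurement per arm at the final day. Both
#' arms are simulated with the basic model under the ground-truth parameters
#' and noisy replicate draws are taken around the noiseless trajectory
#' (negative draws truncated at zero).
#'
#' Defaults mirror the emulated experiment: measurement days 10/13/15, six
#' replicate tumors per arm, proportional Gaussian noise with a relative sd
#' of 0.15 (the published error bars are sizeable but unquantified; 15%
#' keeps calibration realistic yet recoverable).
#'
#' @param truth ground-truth [base_params()].
#' @param init_CD,init_HFD initial states of the arms; by default
#'   [diet_init()] with estrogen derived from the steady state.
#' @param days tumor measurement days; fat is measured once at `max(days)`.
#' @param n_replicates independent replicate tumors per arm and day.
#' @param noise a [noise_model()].
#' @param seed RNG seed; the same seed reproduces the set exactly.
#'
#' @return A `measurement_set`: data frame with columns `arm`, `variable`
#'   (`tumor_volume` / `fat_volume`), `day`, `replicate`, `value`, `sd`,
#'   carrying `truth`, the initial states and `seed` as attributes.
#' @export
#' @examples
#' ms <- generate_experiment(seed = 1)
#' head(ms)
generate_experiment <- function(truth = base_params(),
                                init_CD = diet_init("CD", rounded = FALSE, params = truth),
                                init_HFD = diet_init("HFD", rounded = FALSE, params = truth),
                                days = c(10, 13, 15),
                                n_replicates = 6,
                                noise = noise_model(),
                                seed = 1L) {
  if (n_replicates < 1) stop("generate_experiment: n_replicates must be >= 1", call. = FALSE)
  if (length(days) == 0) stop("generate_experiment: days must be non-empty", call. = FALSE)
  days <- sort(unique(days))
  inits <- list(CD = init_CD, HFD = init_HFD)
  if (!is.null(seed)) set.seed(seed)

  records <- list()
  for (arm in names(inits)) {
    out <- ode_basic_c(inits[[arm]], c(0, days), truth, rtol = 1e-8,
                       atol = 1e-10)
    sim <- as.data.frame(out[-1, , drop = FALSE])
    tumor_clean <- sim$T
    fat_clean <- sim$F[length(days)]
    for (j in seq_along(days)) {
      s <- noise_sd(noise, tumor_clean[j])
      vals <- pmax(tumor_clean[j] + s * rnorm(n_replicates), 0)
      records[[length(records) + 1]] <- data.frame(
        arm = arm, variable = "tumor_volume", day = days[j],
        replicate = seq_len(n_replicates), value = vals, sd = s
      )
    }
    s <- noise_sd(noise, fat_clean)
    records[[length(records) + 1]] <- data.frame(
      arm = arm, variable = "fat_volume", day = max(days),
      replicate = 1L, value = max(fat_clean + s * rnorm(1), 0), sd = s
    )
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  structure(out,
    class = c("measurement_set", "data.frame"),
    truth = truth, inits = inits, noise = noise, seed = seed
  )
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(
    "Synthetic measurement set: %d records (%d tumor, %d fat), seed %s\n",
    nrow(x), sum(x$variable == "tumor_volume"), sum(x$variable == "fat_volume"),
    format(attr(x, "seed"))
  ))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write or read a measurement set
#'
#' Measurements go to CSV (columns `arm`, `variable`, `day`, `replicate`,
#' `value`, `sd`); the generating truth parameters and seed go to a JSON
#' sidecar `<path>.json` so a stored data set stays self-describing.
#'
#' @param ms a `measurement_set`.
#' @param path CSV path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` a `measurement_set` (with truth metadata when the
#'   sidecar is present).
#' @export
write_measurements <- function(ms, path) {
  write.csv(as.data.frame(ms), path, row.names = FALSE)
  truth <- attr(ms, "truth")
  if (!is.null(truth)) {
    side <- list(
      truth = lapply(unclass(truth), as.numeric),
      inits = lapply(attr(ms, "inits"), as.list),
      seed = attr(ms, "seed")
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- read.csv(path)
  out <- structure(df, class = c("measurement_set", "data.frame"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "truth") <- do.call(base_params, as.list(side$truth))
    attr(out, "inits") <- lapply(side$inits, unlist)
    attr(out, "seed") <- side$seed
  }
  out
}
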