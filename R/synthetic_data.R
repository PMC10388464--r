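#' Specification of a synthetic radiomic-clinical cohort
#'
#' Describes the generative model used for testing and calibration: an
#' equicorrelated informative feature block whose mean shifts with the
#' latent class, additional null correlated blocks, i.i.d. Gaussian noise
#' features, binary clinical indicators with class-conditional rates, and a
#' per-class lognormal mutations-per-megabase mechanism thresholded to
#' produce the observed TMB label.
#'
#' @param m sample count.
#' @param n_noise number of pure-noise features.
#' @param blocks list of null correlated blocks, each `c(size, rho)`.
#' @param informative_block `c(size, delta, rho)`: planted block size, mean
#'   shift per feature in the positive class (in within-class SD units), and
#'   within-block correlation.
#' @param clinical_pos,clinical_neg class-conditional Bernoulli rates of the
#'   binary clinical indicators (equal length; length = number of clinical
#'   features).
#' @param prevalence latent positive-class probability.
#' @param tmb_meanlog,tmb_sdlog length-2 lognormal parameters `(low, high)`
#'   for mutations per megabase in the latent negative / positive class.
#' @param cutoff TMB dichotomization cutoff (mut/Mb).
#' @param seed integer seed.
#' @return object of class `nemtie_synthspec`.
#' @export
synthetic_spec <- function(m = 150L,
                           n_noise = 146L,
                           blocks = rep(list(c(size = 8, rho = 0.5)), 6L),
                           informative_block = c(size = 3, delta = 1.5, rho = 0.6),
                           clinical_pos = c(0.60, 0.45, 0.20),
                           clinical_neg = c(0.20, 0.10, 0.50),
                           prevalence = 0.3,
                           tmb_meanlog = c(log(6), log(40)),
                           tmb_sdlog = c(0.55, 0.55),
                           cutoff = 15.5,
                           seed = 1L) {
  stopifnot(m >= 10L, n_noise >= 0L,
            length(clinical_pos) == length(clinical_neg),
            all(clinical_pos >= 0 & clinical_pos <= 1),
            all(clinical_neg >= 0 & clinical_neg <= 1),
            prevalence > 0, prevalence < 1)
  ib <- as.numeric(informative_block)
  names(ib) <- c("size", "delta", "rho")
  if (ib["delta"] < 0) stop("informative delta must be >= 0", call. = FALSE)
  if (ib["rho"] < 0 || ib["rho"] >= 1) stop("rho must lie in [0,1)", call. = FALSE)
  for (b in blocks) {
    if (b[2L] < 0 || b[2L] >= 1) stop("block rho must lie in [0,1)", call. = FALSE)
  }
  structure(
    list(m = as.integer(m), n_noise = as.integer(n_noise), blocks = blocks,
         informative_block = ib, clinical_pos = clinical_pos,
         clinical_neg = clinical_neg, prevalence = prevalence,
         tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
         cutoff = cutoff, seed = as.integer(seed)),
    class = "nemtie_synthspec"
  )
}

#' Default synthetic scenario
#'
#' The acceptance scenario used throughout the test suite: 150 samples, 200
#' features (one planted informative 3-feature block with per-feature mean
#' shift 1.5 and within-block correlation 0.6, six null correlated blocks,
#' 146 noise features, 3 clinical binaries), latent prevalence 0.3, and a
#' lognormal mut/Mb mechanism whose 15.5 mut/Mb cutoff disagrees with the
#' latent class at a rate of about 0.04 (Bayes error of the label channel).
#'
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
default_scenario <- function(seed = 1L) synthetic_spec(seed = seed)

#' Global-null synthetic scenario
#'
#' Identical cohort shape to [default_scenario()] but with the planted mean
#' shift set to 0 and the clinical rates equalized across classes, so the
#' label is independent of every feature. Used for type-I error and p-value
#' calibration checks.
#'
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
null_scenario <- function(seed = 1L) {
  synthetic_spec(informative_block = c(size = 3, delta = 0, rho = 0.6),
                 clinical_pos = c(0.40, 0.30, 0.35),
                 clinical_neg = c(0.40, 0.30, 0.35),
                 seed = seed)
}

#' Total feature count implied by a synthetic spec
#' @param spec a [synthetic_spec()].
#' @return integer.
#' @export
n_features <- function(spec) {
  as.integer(spec$n_noise + spec$informative_block["size"] +
               sum(vapply(spec$blocks, function(b) b[1L], numeric(1))) +
               length(spec$clinical_pos))
}

# equicorrelated Gaussian block via a shared latent factor:
# x_j = sqrt(rho) * g + sqrt(1 - rho) * e_j  =>  cor(x_j, x_k) = rho
equicorr_block <- function(m, size, rho) {
  g <- stats::rnorm(m)
  e <- matrix(stats::rnorm(m * size), m, size)
  sqrt(rho) * g + sqrt(1 - rho) * e
}

#' Generate a synthetic labeled cohort
#'
#' Draws the latent class, the per-class lognormal mutation burden (then
#' thresholded by [label_from_tmb()] to give the observed label `C`), the
#' Gaussian feature blocks and noise, and the clinical binaries. Redraws the
#' whole cohort (up to 100 times) if the realized label prevalence falls
#' outside [0.1, 0.9], so every downstream split is scoreable.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [feature_table()]), `manifest` (data.frame
#'   `feature`, `role`, `category`), `mut_per_mb`, and `latent_class`.
#' @export
#' @examples
#' g <- generate_synthetic(default_scenario(seed = 42))
#' g$table
#' head(subset(g$manifest, role == "informative"))
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "nemtie_synthspec"))
  with_seed(spec$seed, {
    m <- spec$m
    for (attempt in seq_len(100L)) {
      z <- stats::rbinom(m, 1L, spec$prevalence)
      mut <- stats::rlnorm(m,
                           meanlog = spec$tmb_meanlog[z + 1L],
                           sdlog = spec$tmb_sdlog[z + 1L])
      C <- label_from_tmb(mut, spec$cutoff)
      prev <- mean(C)
      if (prev >= 0.1 && prev <= 0.9) break
      if (attempt == 100L) stop("infeasible prevalence after 100 redraws", call. = FALSE)
    }
    ib <- spec$informative_block
    X_inf <- equicorr_block(m, ib["size"], ib["rho"]) + ib["delta"] * z
    blk_list <- lapply(spec$blocks, function(b) equicorr_block(m, b[1L], b[2L]))
    X_noise <- matrix(stats::rnorm(m * spec$n_noise), m, spec$n_noise)
    n_clin <- length(spec$clinical_pos)
    X_clin <- matrix(0, m, n_clin)
    for (j in seq_len(n_clin)) {
      rate <- ifelse(z == 1L, spec$clinical_pos[j], spec$clinical_neg[j])
      X_clin[, j] <- stats::rbinom(m, 1L, rate)
    }
    X <- cbind(X_inf, do.call(cbind, c(blk_list, list(X_noise))), X_clin)
    inf_names <- sprintf("tum_informative_%02d", seq_len(ib["size"]))
    blk_names <- unlist(lapply(seq_along(spec$blocks), function(b) {
      sprintf("tum_block%d_%02d", b, seq_len(spec$blocks[[b]][1L]))
    }))
    noise_names <- sprintf("rim_noise_%03d", seq_len(spec$n_noise))
    clin_names <- sprintf("clinical_%d", seq_len(n_clin))
    fn <- c(inf_names, blk_names, noise_names, clin_names)
    role <- c(rep("informative", length(inf_names)),
              rep("block", length(blk_names)),
              rep("noise", length(noise_names)),
              rep("clinical", length(clin_names)))
    category <- c(rep("tumor_voi", length(inf_names) + length(blk_names)),
                  rep("peritumoral_voi", length(noise_names)),
                  rep("clinical", length(clin_names)))
    tab <- feature_table(X, C, feature_names = fn, feature_category = category)
    list(table = tab,
         manifest = data.frame(feature = fn, role = role, category = category,
                               stringsAsFactors = FALSE),
         mut_per_mb = mut, latent_class = z)
  })
}

#' Write a synthetic cohort and its ground-truth manifest
#'
#' @param gen result of [generate_synthetic()].
#' @param path CSV path for the table; the manifest is written next to it
#'   with suffix `_manifest.csv`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(gen, path) {
  write_feature_table(gen$table, path)
  mpath <- sub("\\.csv$", "_manifest.csv", path)
  if (identical(mpath, path)) mpath <- paste0(path, "_manifest.csv")
  utils::write.csv(gen$manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(path)
}
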