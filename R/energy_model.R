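#' Relative binding energies from bound/unbound counts
#'
#' Under mass-action equilibrium with many sequences competing for one
#' protein pool, the ratio of a variant's counts in the bound and unbound
#' fractions is proportional to its association constant, and the free
#' protein concentration cancels from every ratio of ratios. The relative
#' binding energy of variant x against the reference (consensus) is therefore
#'
#' \deqn{\Delta\Delta G(x) = \ln\frac{N_B(ref)/N_U(ref)}{N_B(x)/N_U(x)}}
#'
#' in units of kT: the reference sits at 0 exactly and weaker binders are
#' positive. A pseudocount keeps energies finite for sparsely observed
#' variants; variants below the read floor are reported missing (`NA`), not
#' zero.
#'
#' @param fc a `fraction_counts` object.
#' @param reference_variant the anchor variant (consensus); must pass
#'   `min_reads` in both fractions.
#' @param pseudocount nonnegative count added to every count entering a
#'   ratio (default 1). Zero is allowed only when all used counts are
#'   positive.
#' @param min_reads minimum raw reads per fraction for a variant's energy to
#'   be reported and used in regression (default 10).
#' @return an object of class `energy_table`: list with `library`,
#'   `reference_variant`, `energies` (data.frame `variant`, `ddG_kT`,
#'   `n_bound`, `n_unbound`, `in_fit`), `pseudocount`, `min_reads`,
#'   `n_used`.
#' @export
relative_energies <- function(fc, reference_variant, pseudocount = 1,
                              min_reads = 10) {
  stopifnot(inherits(fc, "fraction_counts"),
            pseudocount >= 0, min_reads >= 0)
  reference_variant <- clean_seq(reference_variant, what = "reference variant")
  cnt <- fc$counts
  iref <- match(reference_variant, cnt$variant)
  if (is.na(iref)) {
    stop(sprintf("reference %s is not in the library", reference_variant),
         call. = FALSE)
  }
  pass <- cnt$n_bound >= min_reads & cnt$n_unbound >= min_reads
  if (!pass[iref]) {
    stop(sprintf(
      "reference %s has %s bound / %s unbound reads; below min_reads = %d, no energy anchor",
      reference_variant, format(cnt$n_bound[iref]),
      format(cnt$n_unbound[iref]), min_reads), call. = FALSE)
  }
  if (pseudocount == 0 &&
      any(cnt$n_bound[pass] == 0 | cnt$n_unbound[pass] == 0)) {
    stop("pseudocount 0 requires positive counts for every variant passing min_reads",
         call. = FALSE)
  }
  log_odds <- log(cnt$n_bound + pseudocount) - log(cnt$n_unbound + pseudocount)
  ddg <- log_odds[iref] - log_odds
  ddg[!pass] <- NA_real_
  ddg[iref] <- 0 # anchor is exact, not a rounded difference
  structure(
    list(library = fc$library,
         reference_variant = reference_variant,
         energies = data.frame(variant = cnt$variant,
                               ddG_kT = ddg,
                               n_bound = cnt$n_bound,
                               n_unbound = cnt$n_unbound,
                               in_fit = pass,
                               stringsAsFactors = FALSE),
         pseudocount = pseudocount,
         min_reads = as.integer(min_reads),
         n_used = sum(pass)),
    class = "energy_table"
  )
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("Energy table: %d/%d variants measured, reference %s = 0 kT\n",
              x$n_used, nrow(x$energies), x$reference_variant))
  rng <- range(x$energies$ddG_kT, na.rm = TRUE)
  cat(sprintf("  range %.3f .. %.3f kT (pseudocount %g, min_reads %d)\n",
              rng[1], rng[2], x$pseudocount, x$min_reads))
  invisible(x)
}

# Design matrix for the anchored additive model: one indicator column per
# (variable position, non-reference base). The reference base coefficient is
# fixed at 0 by omission, so the model has no intercept and predicts 0 at the
# reference exactly.
epwm_design <- function(variants, reference, positions) {
  refc <- strsplit(reference, "")[[1]]
  varm <- do.call(rbind, strsplit(variants, ""))
  cols <- list()
  for (p in positions) {
    for (b in setdiff(DNA_BASES, refc[p])) {
      cols[[sprintf("p%d.%s", p, b)]] <- as.numeric(varm[, p] == b)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- variants
  X
}

#' Fit an additive energy position weight matrix (ePWM)
#'
#' Least-squares regression of measured relative binding energies on
#' per-position base identity, restricted to variants within `max_mismatch`
#' of the reference. Coefficients are encoded against the reference base
#' (fixed at 0 per position, no intercept), so the fitted model predicts
#' exactly 0 kT for the reference. A base never observed in the neighborhood
#' yields a missing (`NA`) coefficient rather than an extrapolated one.
#'
#' @param et an `energy_table`.
#' @param max_mismatch neighborhood radius around the reference (default 2).
#' @return an object of class `energy_pwm`: list with `positions` (variable
#'   position indices in the core), `beta` (4 x n_positions matrix of energy
#'   contributions in kT, rows A/C/G/T, reference bases 0), `reference_variant`,
#'   `core_pattern`, `fit` (list `r_squared`, `residual_sd`,
#'   `n_variants_fit`).
#' @export
fit_epwm <- function(et, max_mismatch = 2) {
  stopifnot(inherits(et, "energy_table"))
  nb <- hamming_neighborhood(et$reference_variant, et$library, max_mismatch)
  en <- et$energies
  use <- en$variant %in% nb$members & !is.na(en$ddG_kT)
  variants <- en$variant[use]
  y <- en$ddG_kT[use]
  positions <- variable_positions(et$library)
  if (length(positions) == 0) {
    stop("library has no variable positions to fit", call. = FALSE)
  }
  X <- epwm_design(variants, et$reference_variant, positions)
  if (length(y) < ncol(X)) {
    stop(sprintf("only %d usable variants for %d coefficients", length(y),
                 ncol(X)), call. = FALSE)
  }
  # columns never observed are dropped from the solve and reported NA
  seen <- colSums(X) > 0
  fit <- stats::lm.fit(X[, seen, drop = FALSE], y)
  coefs <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  coefs[seen] <- fit$coefficients

  refc <- strsplit(et$reference_variant, "")[[1]]
  beta <- matrix(NA_real_, nrow = 4, ncol = length(positions),
                 dimnames = list(DNA_BASES, paste0("pos", positions)))
  for (j in seq_along(positions)) {
    p <- positions[j]
    beta[refc[p], j] <- 0
    for (b in setdiff(DNA_BASES, refc[p])) {
      beta[b, j] <- coefs[[sprintf("p%d.%s", p, b)]]
    }
  }

  rss <- sum(fit$residuals^2)
  dfree <- length(y) - fit$rank
  tss <- sum((y - mean(y))^2)
  structure(
    list(positions = positions,
         beta = beta,
         reference_variant = et$reference_variant,
         core_pattern = et$library$core_pattern,
         fit = list(
           r_squared = if (tss > 0) 1 - rss / tss else 1,
           residual_sd = if (dfree > 0) sqrt(rss / dfree) else 0,
           n_variants_fit = length(y)
         )),
    class = "energy_pwm"
  )
}

#' @export
print.energy_pwm <- function(x, ...) {
  cat(sprintf("Energy PWM anchored at %s (%d variants fit, R^2 %.4f, residual sd %.4f kT)\n",
              x$reference_variant, x$fit$n_variants_fit, x$fit$r_squared,
              x$fit$residual_sd))
  print(round(x$beta, 3))
  invisible(x)
}

#' Predict additive energies for variants
#'
#' Sums the fitted per-position contributions. Variants touching a base whose
#' coefficient could not be estimated get a missing prediction.
#'
#' @param pwm an `energy_pwm`.
#' @param variants character vector of sequences matching the library's core
#'   pattern.
#' @return numeric vector of energies in kT.
#' @export
predict_energy <- function(pwm, variants) {
  stopifnot(inherits(pwm, "energy_pwm"))
  variants <- clean_seq(variants, what = "variant")
  patc <- strsplit(pwm$core_pattern, "")[[1]]
  fixed <- which(patc != "N")
  out <- numeric(length(variants))
  varm <- do.call(rbind, strsplit(variants, ""))
  if (ncol(varm) != length(patc)) {
    stop("variant length does not match the core pattern", call. = FALSE)
  }
  if (length(fixed) &&
      any(varm[, fixed, drop = FALSE] !=
            matrix(patc[fixed], nrow = nrow(varm), ncol = length(fixed),
                   byrow = TRUE))) {
    stop("variant violates the fixed positions of the core pattern",
         call. = FALSE)
  }
  for (j in seq_along(pwm$positions)) {
    rows <- match(varm[, pwm$positions[j]], DNA_BASES)
    out <- out + pwm$beta[cbind(rows, j)]
  }
  unname(out)
}

#' Mean-centered logo matrix from an energy PWM
#'
#' For display, each variable position's four base energies are shifted to
#' sum to zero; the display matrix is the negation, so preferred (low-energy)
#' bases plot upward. Fixed core positions carry no information and are
#' flagged rather than fitted.
#'
#' @param pwm an `energy_pwm`.
#' @return an object of class `logo_matrix`: list with `energies` (n_core x 4
#'   matrix, centered; `NA` rows at fixed positions), `display` (negated
#'   energies), `fixed_positions` (indices), `core_pattern`.
#' @export
logo_matrix <- function(pwm) {
  stopifnot(inherits(pwm, "energy_pwm"))
  patc <- strsplit(pwm$core_pattern, "")[[1]]
  ncore <- length(patc)
  energies <- matrix(NA_real_, nrow = ncore, ncol = 4,
                     dimnames = list(paste0("pos", seq_len(ncore)), DNA_BASES))
  for (j in seq_along(pwm$positions)) {
    col <- pwm$beta[, j]
    energies[pwm$positions[j], ] <- col - mean(col)
  }
  structure(
    list(energies = energies,
         display = -energies,
         fixed_positions = setdiff(seq_len(ncore), pwm$positions),
         core_pattern = pwm$core_pattern),
    class = "logo_matrix"
  )
}

#' Compare two energy tables (replicates or genotypes)
#'
#' Pairs the variants measured in both tables and reports Pearson
#' correlation, root-mean-square energy difference, a per-experiment noise
#' level, and the best linear fit of `b` on `a`. The noise level assumes the
#' two experiments contribute equal independent noise, so the per-experiment
#' standard deviation is `sd(a - b) / sqrt(2)`; this definition is recorded
#' in the report.
#'
#' @param a,b `energy_table` objects sharing at least 3 measured variants.
#' @param fit `"ols"` (ordinary least squares of b on a, the default) or
#'   `"tls"` (total least squares via the principal axis).
#' @return an object of class `comparison_report`: list with `pearson_r`,
#'   `rms_difference`, `noise_level`, `fit_slope`, `fit_intercept`,
#'   `fit_method`, `noise_definition`, `n_shared`, `pairs` (data.frame
#'   `variant`, `energy_a`, `energy_b`).
#' @export
compare_energy_tables <- function(a, b, fit = c("ols", "tls")) {
  stopifnot(inherits(a, "energy_table"), inherits(b, "energy_table"))
  fit <- match.arg(fit)
  ea <- stats::setNames(a$energies$ddG_kT, a$energies$variant)
  eb <- stats::setNames(b$energies$ddG_kT, b$energies$variant)
  shared <- intersect(names(ea)[!is.na(ea)], names(eb)[!is.na(eb)])
  if (length(shared) < 3) {
    stop(sprintf("only %d variants measured in both tables; need at least 3",
                 length(shared)), call. = FALSE)
  }
  x <- unname(ea[shared])
  y <- unname(eb[shared])
  d <- x - y
  if (fit == "ols") {
    cf <- stats::coef(stats::lm(y ~ x))
    slope <- unname(cf[2]); intercept <- unname(cf[1])
  } else {
    # principal axis of the centered cloud
    pc <- stats::prcomp(cbind(x, y), center = TRUE, scale. = FALSE)
    v <- pc$rotation[, 1]
    slope <- unname(v[2] / v[1])
    intercept <- mean(y) - slope * mean(x)
  }
  structure(
    list(pearson_r = stats::cor(x, y),
         rms_difference = sqrt(mean(d^2)),
         noise_level = stats::sd(d) / sqrt(2),
         fit_slope = slope,
         fit_intercept = intercept,
         fit_method = fit,
         noise_definition = "sd(a - b) / sqrt(2), equal per-experiment noise",
         n_shared = length(shared),
         pairs = data.frame(variant = shared, energy_a = x, energy_b = y,
                            stringsAsFactors = FALSE)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Energy comparison over %d shared variants\n", x$n_shared))
  cat(sprintf("  r = %.3f, rms difference = %.3f kT, noise level = %.3f kT\n",
              x$pearson_r, x$rms_difference, x$noise_level))
  cat(sprintf("  best %s fit: slope %.3f, intercept %.3f kT\n",
              toupper(x$fit_method), x$fit_slope, x$fit_intercept))
  invisible(x)
}
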