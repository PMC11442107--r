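#' Sample same-chromosome marker pairs within a distance cap
#'
#' Draws `n_pairs` marker pairs uniformly without replacement from the set
#' of all same-chromosome pairs separated by at most `max_dist` bp. The
#' pair space is indexed implicitly (never materialized), so sampling
#' 500,000 of billions of eligible pairs is cheap. If fewer eligible pairs
#' exist than requested, all of them are returned.
#'
#' @param g a [genotype_matrix()] with markers sorted by position.
#' @param n_pairs number of pairs to draw. Default 500000.
#' @param max_dist maximum inter-marker distance in bp. Default 10 Mb.
#' @param seed random seed.
#' @return A data frame of class `pair_sample` with columns `chrom`, `i`,
#'   `j` (global marker column indices, `i < j`) and `d` (distance in bp,
#'   `0 < d <= max_dist`).
#' @export
sample_marker_pairs <- function(g, n_pairs = 500000, max_dist = 10e6,
                                seed = 1L) {
  stopifnot(max_dist > 0, n_pairs >= 1)
  mk <- g$markers
  # per left-marker count of eligible right partners, per chromosome
  counts <- integer(nrow(mk))
  for (ch in unique(mk$chrom)) {
    rows <- which(mk$chrom == ch)
    p <- mk$pos[rows]
    counts[rows] <- findInterval(p + max_dist, p) - seq_along(p)
  }
  total <- sum(counts)
  if (total == 0) stop("no eligible marker pairs within max_dist")
  set.seed(seed)
  n_take <- min(n_pairs, total)
  idx <- if (n_take == total) seq_len(total) else sort(sample(total, n_take))
  cum <- cumsum(counts)
  i <- findInterval(idx - 1L, cum) + 1L  # left marker of each sampled pair
  offset <- idx - c(0, cum)[i]           # 1-based rank among i's partners
  j <- i + offset
  d <- mk$pos[j] - mk$pos[i]
  out <- data.frame(chrom = mk$chrom[i], i = i, j = j, d = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_sample", "data.frame")
  out
}

#' Pairwise r-squared for sampled marker pairs
#'
#' For each pair, computes the squared Pearson correlation of the two
#' dosage vectors over accessions non-missing at both markers (composite
#' r-squared; for fully inbred lines with hets masked this equals haplotype
#' r-squared). Pairs with fewer than 2 informative accessions or a
#' monomorphic vector are dropped with a message.
#'
#' @param g the [genotype_matrix()] the pairs refer to.
#' @param pairs a `pair_sample` from [sample_marker_pairs()].
#' @param chunk_size pairs processed per vectorized block. Default 20000.
#' @return `pairs` with an `r2` column added (dropped pairs removed).
#' @export
pairwise_r2 <- function(g, pairs, chunk_size = 20000) {
  m <- nrow(pairs)
  r2 <- numeric(m)
  x <- g$dosage
  storage.mode(x) <- "double"
  for (start in seq(1, m, by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1, m)
    X1 <- x[, pairs$i[rows], drop = FALSE]
    X2 <- x[, pairs$j[rows], drop = FALSE]
    ok <- (!is.na(X1)) & (!is.na(X2))
    X1[!ok] <- 0; X2[!ok] <- 0
    n <- colSums(ok)
    sx <- colSums(X1); sy <- colSums(X2)
    sxx <- colSums(X1 * X1); syy <- colSums(X2 * X2)
    sxy <- colSums(X1 * X2)
    vx <- sxx - sx^2 / n
    vy <- syy - sy^2 / n
    cv <- sxy - sx * sy / n
    r2[rows] <- ifelse(n >= 2 & vx > 0 & vy > 0, cv^2 / (vx * vy), NA_real_)
  }
  dropped <- is.na(r2)
  if (any(dropped)) {
    message(sum(dropped), " pair(s) dropped (uninformative or monomorphic)")
  }
  out <- pairs[!dropped, , drop = FALSE]
  out$r2 <- pmin(r2[!dropped], 1)
  out
}

#' Fit the extended Hill-Weir LD decay model
#'
#' Fits `E[r2] = (r2_high - r2_low) / (1 + d * r_d) + r2_low` to observed
#' (distance, r-squared) pairs by constrained nonlinear least squares
#' ([stats::nls()], port algorithm, box constraints
#' `0 <= r2_low, r2_high <= 1`, `r_d > 0`). Starting values: `r2_high` from
#' the mean r-squared in the closest 1% of distances, `r2_low` from the
#' farthest 1%, `r_d = 1/median(d)`; up to 5 jittered restarts on failure.
#' A flat sample (constant r-squared) degenerates to
#' `r2_high = r2_low = c` with `r_d` unidentifiable and is flagged.
#'
#' @param pairs a data frame with columns `d` and `r2` (e.g. from
#'   [pairwise_r2()]); needs >= 3 pairs with >= 2 distinct distances.
#' @param chromosome label stored on the model. Default `"genome"`.
#' @return An `ld_decay_model`: list with `r2_high`, `r2_low`, `r_d`,
#'   `d_ld50` (`= 1/r_d`), `chromosome`, `rss`, `n_pairs`, `degenerate`.
#' @export
fit_ld_decay <- function(pairs, chromosome = "genome") {
  d <- pairs$d
  r2 <- pairs$r2
  keep <- !is.na(d) & !is.na(r2)
  d <- d[keep]; r2 <- r2[keep]
  if (length(d) < 3 || length(unique(d)) < 2) {
    stop("need at least 3 pairs with at least 2 distinct distances")
  }
  if (stats::sd(r2) < 1e-10) {
    return(structure(list(
      r2_high = mean(r2), r2_low = mean(r2), r_d = NA_real_,
      d_ld50 = NA_real_, chromosome = chromosome, rss = 0,
      n_pairs = length(d), degenerate = TRUE
    ), class = "ld_decay_model"))
  }
  qd <- stats::quantile(d, c(0.01, 0.99))
  rh0 <- mean(r2[d <= qd[1]])
  rl0 <- mean(r2[d >= qd[2]])
  if (!is.finite(rh0)) rh0 <- max(r2)
  if (!is.finite(rl0)) rl0 <- min(r2)
  if (rh0 <= rl0) { rh0 <- max(r2); rl0 <- min(r2) }
  # rescale distance so the rate parameter is O(1) for the optimizer
  d_scale <- stats::median(d)
  dat <- data.frame(ds = d / d_scale, r2 = r2)

  start <- c(rh = min(max(rh0, 1e-4), 1), rl = min(max(rl0, 0), 1), rd = 1)
  best_fit <- NULL
  best_rss <- Inf
  best_err <- NULL
  for (try in 0:5) {
    st <- start
    if (try > 0) {
      st["rh"] <- min(1, max(1e-4, st["rh"] * stats::runif(1, 0.5, 1.5)))
      st["rl"] <- min(1, st["rl"] * stats::runif(1, 0.5, 1.5))
      st["rd"] <- 10^stats::runif(1, -2, 3)
    }
    cand <- tryCatch(
      suppressWarnings(
        stats::nls(r2 ~ (rh - rl) / (1 + ds * rd) + rl, data = dat,
                   start = as.list(st), algorithm = "port",
                   lower = c(rh = 0, rl = 0, rd = .Machine$double.xmin),
                   upper = c(rh = 1, rl = 1, rd = Inf),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE))
      ),
      error = function(e) { best_err <<- e; NULL }
    )
    if (!is.null(cand)) {
      # port stop codes 3-6 are clean convergence; 7 (singular convergence)
      # still yields a least-squares iterate with a flat direction
      code <- cand$convInfo$stopCode
      rss <- sum(stats::resid(cand)^2)
      if ((isTRUE(cand$convInfo$isConv) || code %in% 3:7) &&
          all(is.finite(stats::coef(cand))) && rss < best_rss) {
        best_fit <- cand
        best_rss <- rss
      }
      if (is.null(best_fit)) {
        best_err <- simpleError(cand$convInfo$stopMessage)
      }
    }
  }
  if (is.null(best_fit)) {
    stop("LD decay fit did not converge after restarts: ",
         conditionMessage(best_err))
  }
  fit <- best_fit
  cf <- stats::coef(fit)
  cf["rd"] <- cf["rd"] / d_scale
  if (cf["rl"] > cf["rh"]) cf[c("rh", "rl")] <- cf[c("rl", "rh")]
  # an essentially flat hyperbola leaves r_d unidentifiable: flag it rather
  # than reporting an astronomically large half-decay distance
  degenerate <- cf["rh"] - cf["rl"] < 1e-8 || cf["rd"] < 1e-12
  structure(list(
    r2_high = unname(cf["rh"]), r2_low = unname(cf["rl"]),
    r_d = if (degenerate) NA_real_ else unname(cf["rd"]),
    d_ld50 = if (degenerate) NA_real_ else 1 / unname(cf["rd"]),
    chromosome = chromosome, rss = sum(stats::resid(fit)^2),
    n_pairs = length(d), degenerate = unname(degenerate)
  ), class = "ld_decay_model")
}

#' Predicted r-squared at a physical distance
#'
#' @param object an `ld_decay_model`.
#' @param d distances in bp.
#' @param ... unused.
#' @return `E[r2]` under the fitted hyperbolic decay model.
#' @export
predict.ld_decay_model <- function(object, d, ...) {
  if (object$degenerate) return(rep(object$r2_high, length(d)))
  (object$r2_high - object$r2_low) / (1 + d * object$r_d) + object$r2_low
}

#' @export
print.ld_decay_model <- function(x, ...) {
  cat(sprintf(
    "LD decay model [%s]: r2_high = %.4f, r2_low = %.4f, r_d = %.3g, d_LD50 = %s bp\n",
    x$chromosome, x$r2_high, x$r2_low, x$r_d,
    if (is.na(x$d_ld50)) "NA" else format(round(x$d_ld50), big.mark = ",")
  ))
  invisible(x)
}

#' Half-decay distance of an LD decay model
#'
#' The physical distance at which expected r-squared falls halfway between
#' its fitted maximum and minimum; under the hyperbolic model this is
#' exactly `1 / r_d`. The midpoint identity
#' `E[r2](1/r_d) = (r2_high + r2_low) / 2` is verified to machine precision
#' before returning.
#'
#' @param model an `ld_decay_model` with `r_d > 0`.
#' @return The half-decay distance in bp.
#' @export
d_ld50 <- function(model) {
  if (is.na(model$r_d) || model$r_d <= 0) {
    stop("d_LD50 undefined: r_d is not positive (degenerate or invalid fit)")
  }
  dhalf <- 1 / model$r_d
  mid <- (model$r2_high + model$r2_low) / 2
  stopifnot(isTRUE(all.equal(predict(model, dhalf), mid,
                             tolerance = .Machine$double.eps^0.5)))
  dhalf
}

#' Genome-wide half-decay distance
#'
#' Arithmetic mean of the per-chromosome d_LD50 values. Chromosomes whose
#' fit degenerated to a flat curve (r_d unidentifiable) carry no distance
#' information and are skipped with a warning.
#'
#' @param models a non-empty list of per-chromosome `ld_decay_model`s.
#' @param skip_degenerate drop degenerate chromosome fits instead of
#'   erroring. Default `TRUE`.
#' @return The genome-wide d_LD50 in bp.
#' @export
genome_d_ld50 <- function(models, skip_degenerate = TRUE) {
  if (length(models) == 0) stop("no chromosome models supplied")
  degen <- vapply(models, function(m) isTRUE(m$degenerate), TRUE)
  if (any(degen) && skip_degenerate) {
    warning(sum(degen), " degenerate chromosome fit(s) skipped")
    models <- models[!degen]
    if (length(models) == 0) stop("all chromosome fits are degenerate")
  }
  mean(vapply(models, d_ld50, 0))
}

#' End-to-end LD decay estimation
#'
#' Samples marker pairs genome-wide, computes pairwise r-squared, fits the
#' hyperbolic decay model per chromosome and averages the per-chromosome
#' d_LD50 into a genome-wide value.
#'
#' @param g a [genotype_matrix()].
#' @inheritParams sample_marker_pairs
#' @return A list: `models` (per chromosome), `pairs` (with r2),
#'   `genome_d_ld50`.
#' @export
ld_decay <- function(g, n_pairs = 500000, max_dist = 10e6, seed = 1L) {
  pairs <- sample_marker_pairs(g, n_pairs, max_dist, seed)
  pairs <- pairwise_r2(g, pairs)
  chroms <- unique(pairs$chrom)
  models <- lapply(chroms, function(ch) {
    fit_ld_decay(pairs[pairs$chrom == ch, , drop = FALSE], chromosome = ch)
  })
  names(models) <- chroms
  list(models = models, pairs = pairs, genome_d_ld50 = genome_d_ld50(models))
}
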