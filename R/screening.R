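# Two-way fixed-effects ANOVA (class x channel) computed directly from the
# sums-of-squares decomposition, and per-feature screening of a
# FeatureTable.

#' Balanced two-way ANOVA with interaction
#'
#' Classical fixed-effects decomposition for a balanced two-factor design:
#' `SS_A + SS_B + SS_AB + SS_error = SS_total`, mean squares, F statistics
#' against the error mean square, and p-values from the F distribution.
#' Computed from cell means directly (no model-fitting machinery), which
#' keeps the arithmetic independently checkable.
#'
#' @param values numeric observation vector.
#' @param factorA first factor (e.g. motor-imagery class), coercible to
#'   factor with >= 2 levels.
#' @param factorB second factor (e.g. EEG channel), >= 2 levels.
#' @param alpha significance level recorded on the result (default 0.05).
#' @param featureName label recorded on the result.
#' @return an [AnovaResult-class].
#' @export
twoWayAnova <- function(values, factorA, factorB, alpha = 0.05,
                        featureName = "feature") {
  fa <- factor(factorA); fb <- factor(factorB)
  a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2 || b < 2) stop("each factor needs at least 2 levels")
  if (length(values) != length(fa) || length(values) != length(fb))
    stop("values and factors must have equal length")
  counts <- table(fa, fb)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", levels(fa)[bad[1]], " x ", levels(fb)[bad[2]])
  }
  if (length(unique(as.vector(counts))) != 1)
    stop("design must be balanced (equal observations per cell)")
  r <- counts[1, 1]
  if (r < 2) stop("the interaction term needs >= 2 observations per cell")

  grand <- mean(values)
  meanA <- tapply(values, fa, mean)
  meanB <- tapply(values, fb, mean)
  meanAB <- tapply(values, list(fa, fb), mean)

  ssA <- b * r * sum((meanA - grand)^2)
  ssB <- a * r * sum((meanB - grand)^2)
  ssAB <- r * sum((meanAB - outer(meanA, rep(1, b)) -
                     outer(rep(1, a), meanB) + grand)^2)
  ssE <- sum((values - meanAB[cbind(fa, fb)])^2)
  ssT <- sum((values - grand)^2)

  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfE <- a * b * (r - 1)
  msE <- ssE / dfE
  degenerate <- msE <= .Machine$double.eps * max(ssT, 1)
  if (degenerate)
    warning("zero error mean square: F statistics undefined (degenerate data)")
  Fs <- c(ssA / dfA, ssB / dfB, ssAB / dfAB) / msE
  ps <- stats::pf(Fs, c(dfA, dfB, dfAB), dfE, lower.tail = FALSE)
  if (degenerate) { Fs <- rep(NA_real_, 3); ps <- rep(NA_real_, 3) }

  tb <- data.frame(
    term = c("class", "channel", "interaction", "error", "total"),
    ss = c(ssA, ssB, ssAB, ssE, ssT),
    df = c(dfA, dfB, dfAB, dfE, a * b * r - 1),
    ms = c(ssA / dfA, ssB / dfB, ssAB / dfAB, msE, NA),
    F = c(Fs, NA, NA),
    p = c(ps, NA, NA)
  )
  new("AnovaResult", featureName = featureName, table = tb, alpha = alpha,
      degenerate = degenerate)
}

#' Screen each CompEn feature with a two-way ANOVA
#'
#' Runs [twoWayAnova()] once per feature (FD, Hur, TsEn, DispEn) with
#' factors class and channel, the observations being the per-trial,
#' per-channel feature values. Unbalanced class counts are balanced by
#' seeded down-sampling of the majority classes. The summary names, per
#' feature, the class with the largest standardized deviation of its mean
#' from the grand mean — the class driving significance.
#'
#' @param ft a [FeatureTable-class].
#' @param alpha significance level (default 0.05).
#' @param seed seed for the balancing down-sampler.
#' @return list with `results` (named list of [AnovaResult-class]) and
#'   `summary` (data.frame: feature, p-values per term, significant flag,
#'   driving class).
#' @export
screenFeatures <- function(ft, alpha = 0.05, seed = 1) {
  stopifnot(is(ft, "FeatureTable"))
  labs <- droplevels(ft@labels)
  if (nlevels(labs) < 2) stop("screening needs at least two classes")
  if (min(table(labs)) < 2) stop("screening needs >= 2 trials per class")

  keep <- withSeed(seed, {
    nmin <- min(table(labs))
    unlist(lapply(levels(labs), function(cl) {
      idx <- which(labs == cl)
      if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
    }))
  })
  M <- ft@matrix[keep, , drop = FALSE]
  labs <- labs[keep]

  parts <- strsplit(colnames(M), ".", fixed = TRUE)
  chan <- vapply(parts, `[`, "", 1)
  feat <- vapply(parts, `[`, "", 2)

  results <- list()
  rows <- list()
  for (f in intersect(FEATURE_NAMES, unique(feat))) {
    sel <- which(feat == f)
    values <- as.vector(M[, sel])
    fa <- rep(labs, times = length(sel))
    fb <- rep(chan[sel], each = nrow(M))
    res <- twoWayAnova(values, fa, fb, alpha = alpha, featureName = f)
    results[[f]] <- res
    classMeans <- tapply(values, fa, mean)
    dev <- (classMeans - mean(values)) / stats::sd(values)
    pClass <- res@table$p[1]
    rows[[f]] <- data.frame(
      feature = f,
      pClass = pClass,
      pChannel = res@table$p[2],
      pInteraction = res@table$p[3],
      significant = !is.na(pClass) && pClass < alpha,
      drivingClass = names(which.max(abs(dev)))
    )
  }
  list(results = results, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Per-subject feature report
#'
#' Formats class means and standard deviations per feature with the ANOVA
#' class-effect p-value, one row per (feature, class) — the shape used to
#' summarize per-subject discriminability.
#'
#' @param ft a [FeatureTable-class].
#' @param screening optional output of [screenFeatures()] (recomputed when
#'   missing).
#' @param ... passed to [screenFeatures()].
#' @return data.frame with columns subject, feature, class, mean, sd, p.
#' @export
featureReport <- function(ft, screening = NULL, ...) {
  if (is.null(screening)) screening <- screenFeatures(ft, ...)
  parts <- strsplit(colnames(ft@matrix), ".", fixed = TRUE)
  feat <- vapply(parts, `[`, "", 2)
  out <- list()
  for (f in names(screening$results)) {
    vals <- ft@matrix[, feat == f, drop = FALSE]
    p <- screening$results[[f]]@table$p[1]
    for (cl in levels(ft@labels)) {
      v <- as.vector(vals[ft@labels == cl, ])
      out[[paste(f, cl)]] <- data.frame(
        subject = ft@subjectId, feature = f, class = cl,
        mean = mean(v), sd = stats::sd(v), p = p)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
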