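#' PCA of preprocessed per-cell spectra
#'
#' Mean-centred principal component analysis (no variance scaling) of a
#' samples x channels matrix. Loadings follow the sign convention that each
#' component's largest-magnitude element is positive. At full rank,
#' `scores %*% t(loadings) + center` reconstructs the input to numerical
#' precision.
#'
#' @param mat numeric matrix, one row per sample (cell), one column per
#'   wavenumber channel. A [RamanSpectrumSet-class] is accepted and
#'   transposed internally.
#' @return list of class `spectralPCA`: `loadings` (channels x components,
#'   orthonormal columns), `scores` (samples x components),
#'   `explainedVariance` (fractions, non-increasing), `center`.
#' @export
pcaSpectra <- function(mat) {
  if (is(mat, "RamanSpectrumSet")) mat <- t(intensities(mat))
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2L, all(is.finite(mat)))
  if (all(apply(mat, 2L, stats::sd) == 0))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 explainedVariance = ev, center = pc$center),
            class = "spectralPCA")
}

#' @export
print.spectralPCA <- function(x, ...) {
  cat(sprintf("spectralPCA: %d samples x %d channels, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  ev <- x$explainedVariance[seq_len(min(3L, length(x$explainedVariance)))]
  cat("  leading variance fractions:",
      paste(sprintf("%.1f%%", 100 * ev), collapse = ", "), "\n")
  invisible(x)
}

#' Number of PCs reaching a cumulative variance target
#'
#' @param pca a `spectralPCA` (or numeric vector of variance fractions).
#' @param targetFraction cumulative explained-variance target in (0, 1\];
#'   default 0.91 (the conventional ~91% capture before LDA).
#' @return integer, the smallest k whose cumulative fraction reaches the
#'   target.
#' @export
selectPCs <- function(pca, targetFraction = 0.91) {
  stopifnot(targetFraction > 0, targetFraction <= 1)
  ev <- if (inherits(pca, "spectralPCA")) pca$explainedVariance else pca
  cs <- cumsum(ev)
  k <- which(cs >= targetFraction - 1e-12)[1L]
  if (is.na(k))
    stop(sprintf("target fraction %.3f unreachable (max %.3f)",
                 targetFraction, max(cs)))
  k
}

# pooled-covariance LDA prediction with diagonal shrinkage, used when
# MASS::lda rejects (near-)singular within-class scatter
shrinkageLDAPredict <- function(train, labels, test, gamma = 0.1) {
  classes <- sort(unique(labels))
  p <- ncol(train)
  mus <- lapply(classes, function(cl) colMeans(train[labels == cl, , drop = FALSE]))
  W <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    d <- sweep(train[labels == classes[i], , drop = FALSE], 2L, mus[[i]])
    W <- W + crossprod(d)
  }
  W <- W / (nrow(train) - length(classes))
  repeat {
    Ws <- (1 - gamma) * W + gamma * mean(diag(W)) * diag(p)
    Wi <- tryCatch(solve(Ws), error = function(e) NULL)
    if (!is.null(Wi)) break
    gamma <- min(1, gamma * 2)
  }
  prior <- as.numeric(table(factor(labels, classes))) / length(labels)
  disc <- vapply(seq_along(classes), function(i) {
    d <- sweep(test, 2L, mus[[i]])
    -0.5 * rowSums((d %*% Wi) * d) + log(prior[i])
  }, numeric(nrow(test)))
  classes[max.col(disc)]
}

# fit-and-predict one LDA with graceful shrinkage fallback
ldaPredict <- function(train, labels, test) {
  fit <- tryCatch(
    suppressWarnings(MASS::lda(train, grouping = factor(labels))),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("singular within-class scatter: shrinkage LDA applied")
    return(shrinkageLDAPredict(train, labels, test))
  }
  as.character(stats::predict(fit, test)$class)
}

#' PCA-LDA with leave-one-out cross-validation
#'
#' For each sample, the entire pipeline — centring, PCA, PC-count selection
#' and LDA — is refitted on the remaining samples and the held-out sample is
#' projected and predicted, so no information from the held-out sample leaks
#' into the model that classifies it. Reports the confusion matrix,
#' per-class and overall accuracies, and the LDF scores of a final
#' full-data fit (for plotting).
#'
#' @param mat samples x channels matrix (or [RamanSpectrumSet-class],
#'   transposed internally), typically from [multivariatePreprocess()].
#' @param labels character/factor class labels, one per sample; every class
#'   needs >= 2 samples.
#' @param targetFraction cumulative variance target for PC selection
#'   (default 0.91); applied inside every fold when `nPCs` is NULL.
#' @param nPCs optional fixed PC count overriding the per-fold selection.
#' @return list of class `spectralLDA`: `predictions`, `confusion` (rows =
#'   true class), `perClassAccuracy`, `overallAccuracy` (percent), `nPCs`
#'   (per fold), `ldfScores` (full-data discriminant scores).
#' @export
ldaLoocv <- function(mat, labels, targetFraction = 0.91, nPCs = NULL) {
  if (is(mat, "RamanSpectrumSet")) mat <- t(intensities(mat))
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  stopifnot(nrow(mat) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  if (any(tab < 2L))
    stop("every class needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  n <- nrow(mat)
  preds <- character(n)
  ks <- integer(n)
  for (i in seq_len(n)) {
    pc <- pcaSpectra(mat[-i, , drop = FALSE])
    k <- if (is.null(nPCs)) selectPCs(pc, targetFraction) else nPCs
    kmax <- max(1L, min(n - 1L - length(tab), ncol(pc$scores)))
    k <- min(k, kmax)
    ks[i] <- k
    train <- pc$scores[, seq_len(k), drop = FALSE]
    test <- matrix(mat[i, ] - pc$center, nrow = 1L) %*%
      pc$loadings[, seq_len(k), drop = FALSE]
    preds[i] <- ldaPredict(train, labels[-i], test)
  }
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, classes), factor(preds, classes))
  perClass <- 100 * diag(confusion) / rowSums(confusion)
  overall <- 100 * sum(preds == labels) / n

  pcFull <- pcaSpectra(mat)
  kFull <- if (is.null(nPCs)) selectPCs(pcFull, targetFraction) else nPCs
  kFull <- min(kFull, max(1L, n - length(tab) - 1L))
  ldfScores <- tryCatch({
    fit <- suppressWarnings(
      MASS::lda(pcFull$scores[, seq_len(kFull), drop = FALSE],
                grouping = factor(labels)))
    stats::predict(fit)$x
  }, error = function(e) NULL)

  structure(list(predictions = preds, confusion = confusion,
                 perClassAccuracy = perClass, overallAccuracy = overall,
                 nPCs = ks, ldfScores = ldfScores, labels = labels),
            class = "spectralLDA")
}

#' @export
print.spectralLDA <- function(x, ...) {
  cat(sprintf("spectralLDA: %d samples, %d classes, LOOCV accuracy %.1f%%\n",
              length(x$labels), nrow(x$confusion), x$overallAccuracy))
  print(x$confusion)
  invisible(x)
}
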