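#' Compute a peak intensity ratio with propagated SE
#'
#' `value = I_num / I_den`; the uncertainty is first-order error propagation
#' in quadrature:
#' `se = value * sqrt((se_num/I_num)^2 + (se_den/I_den)^2)`.
#'
#' @param num,den one-row peak-fit results (as returned by [fitWindow()])
#'   for the numerator and denominator bands; both must be converged and the
#'   denominator intensity positive.
#' @param source optional character label (population or cell).
#' @return one-row data.frame: `numerator`, `denominator`, `value`, `se`,
#'   `source`.
#' @export
computePIR <- function(num, den, source = NA_character_) {
  if (!isTRUE(num$converged) || !isTRUE(den$converged))
    stop("both peak fits must be converged")
  if (!is.finite(den$intensity) || den$intensity <= 0)
    stop("undefined ratio: denominator intensity is ", format(den$intensity))
  if (!is.finite(num$intensity) || num$intensity <= 0)
    stop("undefined ratio: numerator intensity is ", format(num$intensity))
  value <- num$intensity / den$intensity
  se <- value * sqrt((num$intensity_se / num$intensity)^2 +
                       (den$intensity_se / den$intensity)^2)
  data.frame(numerator = num$band, denominator = den$band,
             value = value, se = se, source = source,
             stringsAsFactors = FALSE)
}

#' All-pairs PIRs from a band-fit table
#'
#' One PIR per unordered band pair, in the canonical orientation with the
#' lower-wavenumber band as numerator. Non-converged bands are skipped with
#' a warning.
#'
#' @param fits data.frame as from [fitBands()].
#' @param source optional label carried into every PIR row.
#' @return data.frame of PIRs (`choose(k, 2)` rows for k converged bands).
#' @export
allPairsPIRs <- function(fits, source = NA_character_) {
  ok <- fits[fits$converged, , drop = FALSE]
  if (nrow(ok) < nrow(fits))
    warning(sum(!fits$converged), " non-converged band(s) skipped: ",
            paste(fits$band[!fits$converged], collapse = ", "))
  if (nrow(ok) < 2L) stop("need at least 2 converged bands")
  ok <- ok[order(ok$band), , drop = FALSE]
  k <- nrow(ok)
  rows <- vector("list", choose(k, 2L))
  m <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      m <- m + 1L
      rows[[m]] <- computePIR(ok[i, ], ok[j, ], source = source)
    }
  }
  do.call(rbind, rows)
}

#' Reorient a PIR table for display
#'
#' Flips selected rows to `denominator/numerator`; the value inverts and the
#' relative SE is preserved.
#'
#' @param pirs data.frame of PIRs.
#' @param flip logical vector (recycled) selecting rows to invert.
#' @return data.frame.
#' @export
reorientPIRs <- function(pirs, flip = TRUE) {
  flip <- rep_len(flip, nrow(pirs))
  out <- pirs
  v <- pirs$value[flip]
  out$value[flip] <- 1 / v
  out$se[flip] <- pirs$se[flip] / v^2
  out$numerator[flip] <- pirs$denominator[flip]
  out$denominator[flip] <- pirs$numerator[flip]
  out
}

#' Full-discrimination rule
#'
#' TRUE iff the +/- 1 SE intervals of all reference-line values are pairwise
#' disjoint (strict inequality; touching intervals fail). Invariant under a
#' common multiplicative rescaling of values and SEs.
#'
#' @param values numeric PIR values, one per reference line.
#' @param ses matching propagated SEs.
#' @return logical scalar.
#' @export
fullDiscrimination <- function(values, ses) {
  stopifnot(length(values) == length(ses), length(values) >= 2L)
  k <- length(values)
  for (i in seq_len(k - 1L))
    for (j in seq(i + 1L, k))
      if (abs(values[i] - values[j]) <= ses[i] + ses[j]) return(FALSE)
  TRUE
}

#' Group-stratification rule
#'
#' TRUE iff the union of the +/- 1 SE intervals of one group of lines is
#' disjoint (strictly) from the union interval of the other group — the rule
#' that identifies markers separating differentiation-competent from
#' incompetent lines regardless of within-group order.
#'
#' @param values,ses numeric vectors over all lines.
#' @param group1 indices (or logical) of the first group's lines; the rest
#'   form the second group.
#' @return logical scalar.
#' @export
groupStratification <- function(values, ses, group1) {
  stopifnot(length(values) == length(ses))
  if (is.logical(group1)) group1 <- which(group1)
  group2 <- setdiff(seq_along(values), group1)
  stopifnot(length(group1) >= 1L, length(group2) >= 1L)
  lo1 <- min(values[group1] - ses[group1]); hi1 <- max(values[group1] + ses[group1])
  lo2 <- min(values[group2] - ses[group2]); hi2 <- max(values[group2] + ses[group2])
  hi1 < lo2 || hi2 < lo1
}

# classify one band pair across the reference lines
classifyPair <- function(values, ses, groupIdx) {
  if (fullDiscrimination(values, ses)) "full"
  else if (groupStratification(values, ses, groupIdx)) "group"
  else "none"
}

#' Build reference PIR biomarker panels
#'
#' From per-line all-pairs PIR tables, classifies every unordered band pair
#' (full discrimination, group stratification, or none) and assembles, for
#' each reference band, the panel of pairs involving that band whose class
#' is not `"none"`. A pair involving two reference bands legitimately
#' appears in both panels (a message is emitted).
#'
#' @param refPIRs named list of PIR data.frames (one per reference line, as
#'   from [allPairsPIRs()]); names are the line labels.
#' @param referenceBands numeric; default the six panel bands
#'   932, 971, 1060, 1085, 1445, 1473.
#' @param groups list of two character vectors partitioning the line labels;
#'   default [defaultGroups()] on the given names.
#' @return list of [PIRPanel-class] objects, one per reference band.
#' @export
buildPanels <- function(refPIRs,
                        referenceBands = c(932, 971, 1060, 1085, 1445, 1473),
                        groups = defaultGroups(names(refPIRs))) {
  lines <- names(refPIRs)
  if (is.null(lines) || length(lines) < 2L)
    stop("refPIRs must be a named list with one PIR table per reference line")
  if (!setequal(unlist(groups), lines))
    stop("groups must partition the reference line labels")
  groupIdx <- match(groups[[1L]], lines)

  key <- function(d) paste(d$numerator, d$denominator, sep = "/")
  keys <- Reduce(intersect, lapply(refPIRs, key))
  if (!length(keys)) stop("no band pair is present for every reference line")

  pairTab <- do.call(rbind, strsplit(keys, "/"))
  pairTab <- data.frame(numerator = as.numeric(pairTab[, 1L]),
                        denominator = as.numeric(pairTab[, 2L]))
  vals <- sapply(refPIRs, function(d) d$value[match(keys, key(d))])
  ses <- sapply(refPIRs, function(d) d$se[match(keys, key(d))])
  cls <- vapply(seq_along(keys), function(i)
    classifyPair(vals[i, ], ses[i, ], groupIdx), character(1))

  panels <- lapply(referenceBands, function(rb) {
    sel <- (pairTab$numerator == rb | pairTab$denominator == rb) & cls != "none"
    e <- data.frame(numerator = pairTab$numerator[sel],
                    denominator = pairTab$denominator[sel],
                    class = cls[sel], stringsAsFactors = FALSE)
    for (ln in lines) {
      e[[paste0("value_", ln)]] <- vals[sel, ln]
      e[[paste0("se_", ln)]] <- ses[sel, ln]
    }
    new("PIRPanel", referenceBand = rb, entries = e, lines = lines,
        groups = groups)
  })
  names(panels) <- as.character(referenceBands)

  both <- sum(vapply(seq_len(nrow(pairTab)), function(i)
    cls[i] != "none" &&
      pairTab$numerator[i] %in% referenceBands &&
      pairTab$denominator[i] %in% referenceBands, logical(1)))
  if (both > 0)
    message(both, " marker(s) involve two reference bands and appear in two panels")
  panels
}

#' Serialize panels to a versioned JSON file
#'
#' @param panels list of [PIRPanel-class] objects.
#' @param path output path.
#' @param provenance optional named list (fit windows, N per line, ...).
#' @return `path`, invisibly.
#' @export
writePanels <- function(panels, path, provenance = list()) {
  obj <- list(schema = "RamanPIR-panels/1",
              provenance = provenance,
              panels = lapply(panels, function(p)
                list(referenceBand = p@referenceBand,
                     lines = p@lines, groups = p@groups,
                     entries = p@entries)))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read panels written by [writePanels()]
#'
#' @param path JSON file path.
#' @return list of [PIRPanel-class] objects.
#' @export
readPanels <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "RamanPIR-panels/1"))
    stop("unrecognised panel schema: ", obj$schema)
  lapply(obj$panels, function(p) {
    e <- as.data.frame(p$entries)
    if (!nrow(e)) {
      e <- data.frame(numerator = numeric(0), denominator = numeric(0),
                      class = character(0))
      for (ln in p$lines) {
        e[[paste0("value_", ln)]] <- numeric(0)
        e[[paste0("se_", ln)]] <- numeric(0)
      }
    }
    new("PIRPanel", referenceBand = p$referenceBand, entries = e,
        lines = p$lines, groups = lapply(p$groups, unlist))
  })
}
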