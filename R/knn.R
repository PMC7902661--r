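#' Round half-up to whole display units
#'
#' Display rounding for percentage tables (2.5 -> 3), as opposed to base R's
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Match one query PIR to its nearest reference line
#'
#' The matched line is the one minimising `|query value - reference value|`.
#' Equidistant references share the vote equally (and the tie is reported).
#' A match is "within uncertainty" when the distance does not exceed the sum
#' of the query and matched-reference SEs.
#'
#' @param query one-row PIR data.frame (needs `value`, `se`).
#' @param refValues named numeric, one reference value per line.
#' @param refSEs named numeric, matching SEs.
#' @return data.frame with one row per matched line: `line`, `weight`
#'   (1/number of tied lines), `distance`, `within_uncertainty`, `tie`.
#' @export
matchPIR <- function(query, refValues, refSEs) {
  stopifnot(length(refValues) == length(refSEs),
            !is.null(names(refValues)))
  d <- abs(query$value - refValues)
  # ties at floating-point resolution share the vote
  tieTol <- 1e-9 * max(1, abs(query$value))
  matched <- which(d <= min(d) + tieTol)
  data.frame(line = names(refValues)[matched],
             weight = 1 / length(matched),
             distance = unname(d[matched]),
             within_uncertainty = unname(d[matched] <= query$se + refSEs[matched]),
             tie = length(matched) > 1L,
             stringsAsFactors = FALSE)
}

# per-marker nearest-line votes for one panel
panelVotes <- function(queryPIRs, panel) {
  stopifnot(is(panel, "PIRPanel"))
  e <- panel@entries
  qkey <- paste(queryPIRs$numerator, queryPIRs$denominator, sep = "/")
  rows <- list()
  for (i in seq_len(nrow(e))) {
    j <- match(paste(e$numerator[i], e$denominator[i], sep = "/"), qkey)
    if (is.na(j)) {
      warning(sprintf("query has no %g/%g PIR; marker skipped",
                      e$numerator[i], e$denominator[i]))
      next
    }
    refv <- unlist(e[i, paste0("value_", panel@lines)])
    refs <- unlist(e[i, paste0("se_", panel@lines)])
    names(refv) <- names(refs) <- panel@lines
    m <- matchPIR(queryPIRs[j, ], refv, refs)
    m$numerator <- e$numerator[i]
    m$denominator <- e$denominator[i]
    m$panel <- panel@referenceBand
    rows[[length(rows) + 1L]] <- m
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# tally a per-marker vote table into a match result
tallyVotes <- function(perPIR, lines, groups) {
  if (is.null(perPIR) || nrow(perPIR) == 0L)
    stop("no matched markers: cannot compute percentages")
  votes <- vapply(lines, function(ln)
    sum(perPIR$weight[perPIR$line == ln]), numeric(1))
  total <- sum(votes)
  perLine <- 100 * votes / total
  groupPercent <- vapply(groups, function(g) sum(perLine[g]), numeric(1))
  structure(list(
    perPIR = perPIR,
    perLinePercent = perLine,
    groupPercent = groupPercent,
    withinUncertaintyPercent =
      100 * sum(perPIR$weight * perPIR$within_uncertainty) / total,
    nMarkers = total,
    lines = lines, groups = groups
  ), class = "pirMatchResult")
}

#' @export
print.pirMatchResult <- function(x, ...) {
  cat(sprintf("PIR match over %g marker(s):\n", x$nMarkers))
  pl <- roundHalfUp(x$perLinePercent)
  cat(" ", paste(sprintf("%s %g%%", names(pl), pl), collapse = ", "), "\n")
  gp <- roundHalfUp(x$groupPercent)
  cat("  groups:", paste(sprintf("%s %g%%", names(gp), gp), collapse = ", "),
      "\n")
  cat(sprintf("  within uncertainty: %g%%\n",
              roundHalfUp(x$withinUncertaintyPercent)))
  invisible(x)
}

#' Per-panel percentage match
#'
#' Matches every marker of one panel and tallies nearest-line votes into
#' per-line percentages (summing to 100 before rounding), group aggregates,
#' and the fraction of markers matched within uncertainty.
#'
#' @param queryPIRs data.frame of query PIRs in canonical orientation (as
#'   from [allPairsPIRs()]).
#' @param panel a [PIRPanel-class].
#' @return A `pirMatchResult` list: `perPIR` audit table, `perLinePercent`,
#'   `groupPercent`, `withinUncertaintyPercent`, `nMarkers`.
#' @export
percentMatch <- function(queryPIRs, panel) {
  tallyVotes(panelVotes(queryPIRs, panel), panel@lines, panel@groups)
}

#' Pool match results across panels
#'
#' Marker-weighted pooling: all per-marker votes are concatenated and
#' re-tallied, so panels contribute in proportion to their marker counts and
#' group aggregates are computed from unrounded per-line values.
#'
#' @param results list of `pirMatchResult` objects.
#' @return A `pirMatchResult` over all markers.
#' @export
overallMatch <- function(results) {
  stopifnot(length(results) >= 1L)
  perPIR <- do.call(rbind, lapply(results, `[[`, "perPIR"))
  tallyVotes(perPIR, results[[1L]]$lines, results[[1L]]$groups)
}

#' Classify a query against a set of reference panels
#'
#' Runs [percentMatch()] per panel and [overallMatch()] across panels.
#' Panels none of whose markers are present in the query are dropped with a
#' warning.
#'
#' @param queryPIRs data.frame of query PIRs (canonical orientation).
#' @param panels list of [PIRPanel-class] objects.
#' @return list with `perPanel` (named list of `pirMatchResult`) and
#'   `overall` (`pirMatchResult`).
#' @export
classifyAgainstPanels <- function(queryPIRs, panels) {
  perPanel <- list()
  for (nm in names(panels)) {
    v <- panelVotes(queryPIRs, panels[[nm]])
    if (is.null(v)) {
      warning("panel ", nm, " has no matchable marker; dropped")
      next
    }
    perPanel[[nm]] <- tallyVotes(v, panels[[nm]]@lines, panels[[nm]]@groups)
  }
  if (!length(perPanel)) stop("no panel produced any match")
  list(perPanel = perPanel, overall = overallMatch(perPanel))
}

#' Aggregate per-line match percentages into group matches
#'
#' Pools per-line percentages (unrounded) into the two biological groups;
#' used both internally and to aggregate externally tabulated per-line
#' percentages.
#'
#' @param perLine named numeric of per-line percentages.
#' @param groups list of two character vectors of line names; defaults to
#'   lines 1+3 vs 2+4 of `names(perLine)` when `NULL` (the conventional
#'   Y101/Y201 vs Y102/Y202 column order Y101, Y102, Y201, Y202).
#' @return named numeric of length 2 (sums to `sum(perLine)`).
#' @export
groupMatchPercent <- function(perLine, groups = NULL) {
  if (is.null(groups)) {
    stopifnot(length(perLine) == 4L)
    nm <- names(perLine)
    groups <- list(paste(nm[1], nm[3], sep = "/"), paste(nm[2], nm[4], sep = "/"))
    out <- c(perLine[1] + perLine[3], perLine[2] + perLine[4])
    names(out) <- unlist(groups)
    return(out)
  }
  vapply(groups, function(g) sum(perLine[g]), numeric(1))
}

#' Export a Table-style classification summary as CSV
#'
#' One row per query with per-line and group percentages, display-rounded to
#' whole percent (half-up).
#'
#' @param results named list of classification results (each as returned by
#'   [classifyAgainstPanels()]).
#' @param path output CSV path.
#' @return the summary data.frame, invisibly.
#' @export
writeMatchTable <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    ov <- results[[nm]]$overall
    c(list(query = nm),
      as.list(roundHalfUp(ov$perLinePercent)),
      as.list(roundHalfUp(ov$groupPercent)),
      list(within_uncertainty = roundHalfUp(ov$withinUncertaintyPercent),
           n_markers = ov$nMarkers))
  })
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
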