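#' Two-sample Student t-test
#'
#' Pooled-variance (Student) two-sided two-sample t-test, the default
#' group-comparison statistic throughout the package; Welch is available
#' for sensitivity checks. Degenerate inputs (zero pooled variance) give
#' t = 0 / p = 1 when the means agree and are flagged otherwise.
#'
#' @param x,y numeric samples (each length >= 2, finite).
#' @param welch use Welch's unequal-variance test instead.
#' @return list with t, p, meanX, meanY, sdX, sdY, direction
#'   (\code{"increase"}/\code{"decrease"}/\code{"none"}, sign of
#'   mean(x) - mean(y)) and a degenerate flag.
#' @examples
#' twoSampleTtest(c(1, 2, 3), c(11, 12, 13))$t  # -12.25
#' @export
twoSampleTtest <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  degenerate <- FALSE
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) { t <- 0; p <- 1 }
    else { t <- sign(mean(x) - mean(y)) * Inf; p <- .Machine$double.xmin
           degenerate <- TRUE }
  } else {
    ht <- stats::t.test(x, y, var.equal = !welch)
    t <- unname(ht$statistic); p <- ht$p.value
  }
  dx <- mean(x) - mean(y)
  list(t = t, p = p, meanX = mean(x), meanY = mean(y),
       sdX = stats::sd(x), sdY = stats::sd(y),
       direction = if (dx > 0) "increase" else if (dx < 0) "decrease" else "none",
       degenerate = degenerate)
}

#' Identify hub nodes
#'
#' A node is a hub when its value (group-mean degree or betweenness)
#' exceeds the across-node mean plus one sample standard deviation. A
#' constant vector yields an empty hub set; the rule is invariant under
#' affine rescaling of the node values.
#'
#' @param nodeValues numeric vector over the N nodes (N >= 2).
#' @param metric,group optional labels stored in the result.
#' @return list with hubs (node indices), cutoff, metric and group.
#' @examples
#' identifyHubs(c(1, 1, 1, 1, 10))$hubs  # node 5
#' @export
identifyHubs <- function(nodeValues, metric = "degree", group = NA_character_) {
  if (length(nodeValues) < 2) stop("need >= 2 nodes")
  cutoff <- mean(nodeValues) + stats::sd(nodeValues)
  list(hubs = which(nodeValues > cutoff), cutoff = cutoff,
       metric = metric, group = group)
}

#' Group-mean nodal metric maps
#'
#' Per-node arithmetic means of a nodal metric within each group, plus the
#' case-minus-control difference map (the numbers behind group degree /
#' betweenness maps).
#'
#' @param nodalValues numeric matrix, subjects x nodes (no missing values).
#' @param groups character group label per subject (two groups).
#' @param case label of the case group (default \code{"PD"}).
#' @return data.frame with node, meanCase, meanControl, difference.
#' @export
groupMeanNodal <- function(nodalValues, groups, case = "PD") {
  if (anyNA(nodalValues)) stop("missing nodal values")
  stopifnot(nrow(nodalValues) == length(groups))
  lv <- unique(groups)
  if (length(lv) != 2 || !case %in% lv) stop("need two groups incl. '", case, "'")
  control <- setdiff(lv, case)
  mc <- colMeans(nodalValues[groups == case, , drop = FALSE])
  mn <- colMeans(nodalValues[groups == control, , drop = FALSE])
  data.frame(node = seq_along(mc), meanCase = mc, meanControl = mn,
             difference = mc - mn, row.names = NULL)
}

#' Edgewise group comparison of connectivity matrices
#'
#' One pooled-variance t-test per upper-triangle edge between the case and
#' control groups, with uncorrected two-sided p values (an FDR-adjusted
#' column may be requested additionally) and the direction of the effect in
#' cases, matching the increased/decreased edge-colouring convention.
#'
#' @param wMatrices list of [ConnectivityMatrix-class] (or plain matrices),
#'   one per subject, identical node order.
#' @param groups group label per subject.
#' @param case case-group label (default \code{"PD"}).
#' @param fdr if TRUE, add a Benjamini-Hochberg adjusted p column
#'   (off by default; the primary convention is uncorrected p).
#' @return data.frame, one row per edge (i, j), sorted as the canonical
#'   upper-triangle order: i, j, t, p, meanCase, meanControl, sdCase,
#'   sdControl, direction.
#' @export
edgewiseGroupTest <- function(wMatrices, groups, case = "PD", fdr = FALSE) {
  stopifnot(length(wMatrices) == length(groups))
  lv <- unique(groups)
  if (length(lv) != 2 || !case %in% lv) stop("need two groups incl. '", case, "'")
  if (min(table(groups)) < 2) stop("need >= 2 subjects per group")
  getW <- function(x) if (is(x, "ConnectivityMatrix")) x@W else x
  n <- nrow(getW(wMatrices[[1]]))
  pairs <- upperPairs(n)
  feat <- t(vapply(wMatrices, function(x) getW(x)[pairs],
                   numeric(nrow(pairs))))
  res <- colTtests(feat[groups == case, , drop = FALSE],
                   feat[groups != case, , drop = FALSE])
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], t = res$t, p = res$p,
                    meanCase = res$meanX, meanControl = res$meanY,
                    sdCase = res$sdX, sdControl = res$sdY,
                    direction = ifelse(res$meanX > res$meanY, "increase",
                                ifelse(res$meanX < res$meanY, "decrease",
                                       "none")))
  if (fdr) out$pAdjusted <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Export an edge list for circular-plot tools
#'
#' Formats a set of tested edges as abbreviation pairs with signed weight
#' (positive = increased in cases, negative = decreased), the input format
#' of circular connectogram plotting tools.
#'
#' @param edgeTests data.frame from [edgewiseGroupTest()] (typically
#'   filtered to significant edges).
#' @param lookup ROI lookup table (default [aalLookup()]).
#' @return data.frame with from, to, signedWeight.
#' @export
formatEdgeListForPlot <- function(edgeTests, lookup = aalLookup()) {
  ab <- lookup$abbreviation[match(edgeTests$i, lookup$code)]
  ab2 <- lookup$abbreviation[match(edgeTests$j, lookup$code)]
  ab[is.na(ab)] <- as.character(edgeTests$i[is.na(ab)])
  ab2[is.na(ab2)] <- as.character(edgeTests$j[is.na(ab2)])
  data.frame(from = ab, to = ab2,
             signedWeight = sign(edgeTests$meanCase - edgeTests$meanControl) *
               abs(edgeTests$t))
}
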