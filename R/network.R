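#' Signed expression difference between two conditions
#'
#' Per-gene difference of replicate means of normalized expression
#' (default S12 - L12, the contrast superimposed on the regulatory network).
#' Differences smaller in magnitude than `tau` are called unchanged (sign 0).
#'
#' @param x normalized (rounded) expression matrix, genes x samples
#' @param conditions condition label per column
#' @param condA,condB conditions defining the difference A - B
#' @param tau change-call threshold on the normalized scale (default 1)
#' @return data.frame: `gene`, `delta`, `sign` (-1, 0, 1)
#' @export
deltaExpression <- function(x, conditions, condA = "S12", condB = "L12",
                            tau = 1) {
  stopifnot(tau >= 0)
  mA <- rowMeans(x[, conditions == condA, drop = FALSE])
  mB <- rowMeans(x[, conditions == condB, drop = FALSE])
  d <- mA - mB
  sgn <- ifelse(abs(d) < tau, 0L, ifelse(d > 0, 1L, -1L))
  data.frame(gene = rownames(x), delta = unname(d), sign = unname(sgn),
             stringsAsFactors = FALSE)
}

#' Project a reference regulatory network through an ortholog map
#'
#' An edge survives exactly when both its endpoints have orthologs in the
#' study organism; surviving edges are renamed to study gene identifiers with
#' signs preserved. By default many-to-many ortholog assignments are dropped
#' so the map is a bijection on its domain. Self-edges (autoregulation) are
#' legitimate and kept. The numbers of dropped map entries and edges are
#' attached as `metadata`.
#'
#' @param reference a [RegulatoryNetwork-class] in reference gene ids
#' @param orthologs data.frame with columns `reference`, `study`
#' @param oneToOne drop reference or study genes appearing more than once in
#'   the map (default TRUE)
#' @return the projected `RegulatoryNetwork` (study ids); attribute
#'   `projection` on the edge table records `edges_dropped` and
#'   `map_entries_dropped`
#' @export
projectNetwork <- function(reference, orthologs, oneToOne = TRUE) {
  stopifnot(is(reference, "RegulatoryNetwork"),
            all(c("reference", "study") %in% names(orthologs)))
  om <- orthologs
  dropped_map <- 0L
  if (oneToOne) {
    dup <- duplicated(om$reference) | duplicated(om$reference, fromLast = TRUE) |
      duplicated(om$study) | duplicated(om$study, fromLast = TRUE)
    dropped_map <- sum(dup)
    om <- om[!dup, , drop = FALSE]
  }
  toStudy <- stats::setNames(om$study, om$reference)
  e <- networkEdges(reference)
  keep <- e$regulator %in% names(toStudy) & e$target %in% names(toStudy)
  out <- data.frame(regulator = unname(toStudy[e$regulator[keep]]),
                    target = unname(toStudy[e$target[keep]]),
                    sign = e$sign[keep], stringsAsFactors = FALSE)
  net <- regulatoryNetwork(out)
  attr(net@edges, "projection") <- list(edges_dropped = sum(!keep),
                                        map_entries_dropped = dropped_map)
  net
}

#' Keep regulatory edges whose sign agrees with observed expression changes
#'
#' An edge is retained when both endpoints show a called expression change
#' (nonzero sign at threshold `tau` of [deltaExpression()]) and the edge sign
#' is compatible: activation requires regulator and target to change in the
#' same direction, repression in opposite directions, and a dual edge is
#' compatible with any combination of changes. With
#' `requireBothEndpoints = FALSE` only the target must change; an edge whose
#' regulator is unchanged is then kept regardless of sign.
#'
#' @param net a [RegulatoryNetwork-class] in study gene ids
#' @param delta data.frame from [deltaExpression()]; genes missing from it are
#'   treated as unchanged
#' @param requireBothEndpoints default TRUE (agreement needs an observed
#'   change on both ends)
#' @return the filtered `RegulatoryNetwork`
#' @export
signConsistencyFilter <- function(net, delta, requireBothEndpoints = TRUE) {
  stopifnot(is(net, "RegulatoryNetwork"))
  e <- networkEdges(net)
  sgn <- stats::setNames(delta$sign, delta$gene)
  rs <- sgn[e$regulator]; rs[is.na(rs)] <- 0L
  ts <- sgn[e$target]; ts[is.na(ts)] <- 0L
  agree <- (e$sign == "activation" & rs == ts) |
    (e$sign == "repression" & rs == -ts) |
    (e$sign == "dual")
  keep <- if (requireBothEndpoints) {
    rs != 0L & ts != 0L & agree
  } else {
    ts != 0L & (rs == 0L | agree)
  }
  regulatoryNetwork(e[keep, , drop = FALSE])
}

#' Most connected hub regulators
#'
#' Regulators ranked by number of regulatory connections (out-degree by
#' default; `mode = "total"` also counts edges where the gene is itself a
#' target). Ties are broken lexicographically.
#'
#' @param net a [RegulatoryNetwork-class]
#' @param topN how many regulators to return (default 5)
#' @param mode `"out"` (regulatory targets) or `"total"` degree
#' @return data.frame: `regulator`, `connections`, ranked
#' @export
hubRegulators <- function(net, topN = 5, mode = c("out", "total")) {
  mode <- match.arg(mode)
  if (topN <= 0) stop("topN must be positive")
  e <- networkEdges(net)
  if (!nrow(e))
    return(data.frame(regulator = character(), connections = integer()))
  deg <- table(e$regulator)
  if (mode == "total") {
    tdeg <- table(e$target[e$target %in% names(deg)])
    deg[names(tdeg)] <- deg[names(tdeg)] + tdeg
  }
  df <- data.frame(regulator = names(deg), connections = as.integer(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$connections, df$regulator), , drop = FALSE]
  rownames(df) <- NULL
  head(df, topN)
}

#' Regulators sharing targets with a query target set
#'
#' Used to find substitutes for a regulator missing from the study genome:
#' each regulator is scored by the Jaccard overlap between its target set and
#' the query set, `|T_r and Q| / |T_r or Q|`, and ranked descending with
#' lexicographic tie-breaking.
#'
#' @param net a [RegulatoryNetwork-class]
#' @param targetSet nonempty character vector of query target genes
#' @param topN number of candidates to return (default 5)
#' @return data.frame: `regulator`, `jaccard`, `shared`
#' @export
sharedTargetRegulators <- function(net, targetSet, topN = 5) {
  if (!length(targetSet)) stop("targetSet must be nonempty")
  e <- networkEdges(net)
  tl <- split(e$target, e$regulator)
  j <- vapply(tl, function(tg) {
    tg <- unique(tg)
    length(intersect(tg, targetSet)) / length(union(tg, targetSet))
  }, numeric(1))
  sh <- vapply(tl, function(tg) length(intersect(unique(tg), targetSet)), 1L)
  df <- data.frame(regulator = names(tl), jaccard = unname(j),
                   shared = unname(sh), stringsAsFactors = FALSE)
  df <- df[order(-df$jaccard, df$regulator), , drop = FALSE]
  rownames(df) <- NULL
  head(df, topN)
}
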