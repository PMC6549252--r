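# Threshold-based species/geovar delimitation from similarity matrices:
# the standard >= 70% in silico DDH cut-off for "same species", with the
# 97% / 98.7% 16S rRNA identity thresholds as the marker-gene screen.

#' Cluster isolates at a similarity threshold
#'
#' Single linkage groups isolates into the connected components of the
#' graph with an edge wherever pairwise similarity >= threshold (the
#' conventional reading of "share >= 70% DDH"). Complete linkage merges
#' groups agglomeratively only while every cross pair satisfies the
#' threshold, taking the best-supported merge first and breaking ties
#' lexicographically. Comparisons are inclusive (>=), and output order is
#' deterministic: members sorted within groups, groups sorted by first
#' member.
#'
#' @param m a [labeled_matrix()] of kind `similarity_percent`.
#' @param threshold similarity cut-off in \[0, 100\].
#' @param linkage `"single"` (default) or `"complete"`.
#' @return an object of class `cluster_set`: `partition` (list of label
#'   groups), `threshold`, `linkage`, `matrix_kind`.
#' @export
#' @examples
#' fx <- packaged_fixtures()
#' cluster_at_threshold(fx$ddh_matrix, 70)   # 5 species-level groups
cluster_at_threshold <- function(m, threshold,
                                 linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (m$kind != "similarity_percent")
    gv_stop("clustering expects a similarity_percent matrix, got ", m$kind)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 100)
    gv_stop("threshold must be a single value in [0, 100]")
  labs <- sort(m$labels)
  v <- m$values[labs, labs, drop = FALSE]
  n <- length(labs)
  if (linkage == "single") {
    adj <- v >= threshold
    comp <- integer(n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (comp[s]) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        nb <- which(adj[i, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    groups <- split(labs, comp)
  } else {
    groups <- as.list(labs)
    repeat {
      best <- NULL
      k <- length(groups)
      if (k < 2) break
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        s <- min(v[groups[[i]], groups[[j]]])
        if (s >= threshold && (is.null(best) || s > best$s))
          best <- list(s = s, i = i, j = j)
      }
      if (is.null(best)) break
      merged <- sort(c(groups[[best$i]], groups[[best$j]]))
      groups <- groups[-c(best$i, best$j)]
      groups <- c(groups, list(merged))
      groups <- groups[order(vapply(groups, `[`, character(1), 1))]
    }
  }
  groups <- lapply(unname(groups), sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  structure(list(partition = groups, threshold = threshold,
                 linkage = linkage, matrix_kind = m$kind),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d group(s) at threshold %g%% (%s linkage)\n",
              length(x$partition), x$threshold, x$linkage))
  for (i in seq_along(x$partition))
    cat(sprintf("  %d: %s\n", i, paste(x$partition[[i]], collapse = ", ")))
  invisible(x)
}

#' Extreme pairwise value within or between label groups
#'
#' The minimum (or maximum) matrix entry over all unordered pairs within
#' `members`, or — when `others` is given — over all `members` x `others`
#' pairs. Reports the achieving pair, lexicographically first on ties.
#' Used, e.g., to verify that a clade shares "more than X%" similarity or
#' that outgroup strains stay below a cut-off.
#'
#' @param m a [labeled_matrix()].
#' @param members character vector of labels (a subset of `m$labels`).
#' @param others optional second, disjoint label set.
#' @param mode `"min"` or `"max"`.
#' @return a list with `value` and `pair` (character vector of length 2).
#' @export
#' @examples
#' fx <- packaged_fixtures()
#' group_extreme(fx$ddh_matrix, c("SolV", "Fur", "Rib", "Fdl", "Ice"))
group_extreme <- function(m, members, others = NULL,
                          mode = c("min", "max")) {
  mode <- match.arg(mode)
  miss <- setdiff(c(members, others), m$labels)
  if (length(miss))
    gv_stop("labels not in matrix: ", paste(miss, collapse = ", "))
  members <- sort(unique(members))
  if (is.null(others)) {
    if (length(members) < 2)
      gv_stop("need at least 2 members for a within-group extreme")
    pairs <- t(utils::combn(members, 2))
  } else {
    others <- sort(unique(others))
    overlap <- intersect(members, others)
    if (length(overlap))
      gv_stop("member and other sets overlap: ",
              paste(overlap, collapse = ", "))
    pairs <- as.matrix(expand.grid(members, others, stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  vals <- m$values[cbind(pairs[, 1], pairs[, 2])]
  idx <- if (mode == "min") which(vals == min(vals)) else
    which(vals == max(vals))
  best <- idx[1]  # pairs are in lexicographic order
  list(value = vals[best], pair = unname(c(pairs[best, 1], pairs[best, 2])))
}

#' Classify the relationship of two isolates from 16S identity and DDH
#'
#' Decision table (all comparisons inclusive, thresholds configurable):
#' DDH is authoritative when available — `same_species` when
#' `ddh >= ddh_species` (70% by default), `distinct_species` otherwise.
#' When the 16S identity meets the modern species cutoff
#' (`s16_species`, 98.7%) but DDH falls below the species line, the
#' result carries an `ambiguous_16s` flag: the marker gene suggests one
#' species while genome-scale similarity separates them. With DDH
#' missing (`NA`), 16S alone decides: `same_species` at or above
#' `s16_species`, `distinct_species` below the classic `s16_classic`
#' threshold (97%), `ambiguous` in between.
#'
#' Two isolates already known to come from geographically separated
#' sites that still satisfy the species thresholds are geovar
#' (geographic variant) candidates; pass `allopatric = TRUE` to label
#' them `same_geovar_candidate` instead of `same_species`.
#'
#' @param s16 16S rRNA identity (%).
#' @param ddh in silico DDH value (%), or `NA` if unavailable.
#' @param thresholds list with `ddh_species`, `s16_species`, `s16_classic`.
#' @param allopatric set `TRUE` when the pair is known to originate from
#'   separated sampling sites.
#' @return a list with `label` (one of `same_species`,
#'   `same_geovar_candidate`, `distinct_species`, `ambiguous`) and
#'   `flags` (character vector; may contain `"ambiguous_16s"`).
#' @export
#' @examples
#' classify_relationship(99.5, 61)   # distinct species, ambiguous 16S
classify_relationship <- function(s16, ddh,
                                  thresholds = list(ddh_species = 70,
                                                    s16_species = 98.7,
                                                    s16_classic = 97),
                                  allopatric = FALSE) {
  if (!is.na(s16) && (s16 < 0 || s16 > 100)) gv_stop("s16 out of [0, 100]")
  if (!is.na(ddh) && (ddh < 0 || ddh > 100)) gv_stop("ddh out of [0, 100]")
  th <- thresholds
  flags <- character()
  if (is.na(ddh)) {
    label <- if (!is.na(s16) && s16 >= th$s16_species) "same_species"
    else if (!is.na(s16) && s16 < th$s16_classic) "distinct_species"
    else "ambiguous"
  } else if (ddh >= th$ddh_species) {
    label <- if (allopatric) "same_geovar_candidate" else "same_species"
  } else {
    label <- "distinct_species"
    if (!is.na(s16) && s16 >= th$s16_species) flags <- "ambiguous_16s"
  }
  list(label = label, flags = flags)
}

#' Write a cluster set as a two-column TSV
#' @param cs a `cluster_set`.
#' @param path output path (columns `label`, `group`).
#' @return `path`, invisibly.
#' @export
write_cluster_set <- function(cs, path) {
  df <- data.frame(
    label = unlist(cs$partition),
    group = rep(seq_along(cs$partition), lengths(cs$partition))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
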