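# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms from the package code:
# spherical law of cosines vs haversine, exhaustive path enumeration vs
# Gotoh dynamic programming, textbook Pearson-on-upper-triangles vs the
# standardized Mantel sum, transitive closure vs breadth-first search.

R_KM <- 6371.0088

# spherical law of cosines great-circle distance (km)
slc_km <- function(a, b) {
  la <- a[["lat"]] * pi / 180; lb <- b[["lat"]] * pi / 180
  dl <- (b[["lon"]] - a[["lon"]]) * pi / 180
  x <- sin(la) * sin(lb) + cos(la) * cos(lb) * cos(dl)
  R_KM * acos(pmin(pmax(x, -1), 1))
}

# random symmetric labeled distance matrix with zero diagonal
rand_dist_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  ut <- upper.tri(v)
  v[ut] <- runif(sum(ut), 0, 100)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  labeled_matrix(v, kind = "distance_percent")
}

# random similarity matrix (diag 100)
rand_sim_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  v <- matrix(100, n, n, dimnames = list(labels, labels))
  ut <- upper.tri(v)
  v[ut] <- runif(sum(ut), 0, 99.9)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  labeled_matrix(v, kind = "similarity_percent")
}

# Pearson correlation of the vectorized upper triangles (textbook Mantel)
oracle_mantel_r <- function(x, y) {
  cor(x$values[upper.tri(x$values)], y$values[upper.tri(y$values)])
}

# all permutations of 1:n (lexicographic), independent generator
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# exact one-sided (greater) permutation p by direct enumeration
oracle_exhaustive_p <- function(x, y) {
  ux <- x$values[upper.tri(x$values)]
  r_obs <- cor(ux, y$values[upper.tri(y$values)])
  n <- nrow(y$values)
  rs <- vapply(oracle_perms(n), function(p) {
    pv <- y$values[p, p]
    cor(ux, pv[upper.tri(pv)])
  }, numeric(1))
  mean(rs >= r_obs)
}

# connected components at a similarity threshold via transitive closure
oracle_components <- function(values, threshold) {
  adj <- values >= threshold
  diag(adj) <- TRUE
  reach <- adj
  n <- nrow(values)
  for (k in seq_len(n)) reach <- (reach %*% adj) > 0
  labs <- rownames(values)
  comp <- apply(reach, 1, function(r) paste(sort(labs[r]), collapse = "|"))
  groups <- lapply(unique(unname(comp)), function(g) strsplit(g, "|",
                                                              fixed = TRUE)[[1]])
  groups[order(vapply(groups, `[`, character(1), 1))]
}

# minimum spanning tree total length (Prim), oracle for the
# colonization tree's total length lower bound
oracle_mst_total <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  while (!all(in_tree)) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    total <- total + min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  total
}

# Exhaustive global-alignment score by enumerating all monotone
# alignment paths. Gap run of length L costs open + (L - 1) * extend;
# with free end gaps the same-direction run at the very start and the
# run forced once a sequence is exhausted cost nothing.
oracle_align_score <- function(a, b, params = alignment_params()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  mt <- params$match; mm <- params$mismatch
  op <- params$gap_open; ex <- params$gap_extend
  free <- params$end_gaps == "free"
  best <- -Inf
  rec <- function(i, j, prev, score) {
    if (i == n && j == m) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i == n) {             # only horizontal gap columns remain
      rem <- m - j
      cost <- if (free) 0 else if (prev == "Y") rem * ex else
        op + (rem - 1) * ex
      if (score + cost > best) best <<- score + cost
      return(invisible(NULL))
    }
    if (j == m) {
      rem <- n - i
      cost <- if (free) 0 else if (prev == "X") rem * ex else
        op + (rem - 1) * ex
      if (score + cost > best) best <<- score + cost
      return(invisible(NULL))
    }
    s <- if (A[i + 1] == B[j + 1] && A[i + 1] != "N") mt else mm
    rec(i + 1, j + 1, "M", score + s)
    leadX <- free && prev %in% c("S", "LX")
    rec(i + 1, j, if (leadX) "LX" else "X",
        score + if (leadX) 0 else if (prev == "X") ex else op)
    leadY <- free && prev %in% c("S", "LY")
    rec(i, j + 1, if (leadY) "LY" else "Y",
        score + if (leadY) 0 else if (prev == "Y") ex else op)
  }
  rec(0L, 0L, "S", 0)
  best
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
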