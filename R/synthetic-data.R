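# Synthetic isolation-by-distance datasets: site placement on the
# sphere, a stepping-stone colonization tree, and Jukes-Cantor sequence
# evolution whose per-edge substitution probability grows with the
# great-circle length of the colonization step. Every pipeline stage can
# be exercised against data with known ground truth, and the per-km
# substitution rate can be re-estimated from the output (recover_mu).

#' Parameters for an isolation-by-distance simulation
#'
#' The divergence model: sites are colonized along a spanning tree
#' (each new site from its nearest already-colonized site), and along an
#' edge of great-circle length g km each nucleotide substitutes with
#' probability `p(g) = (3/4) * (1 - exp(-(4/3) * mu * g / 1000))` — the
#' Jukes-Cantor transition probability after `mu * g / 1000` expected
#' substitutions per site. `mu` is therefore expressed per 1000 km of
#' colonization path, a human-scale unit for site separations of
#' 10^3–10^4 km.
#'
#' @param n_sites number of sites (>= 3).
#' @param placement `"uniform_sphere"` (area-uniform random points) or
#'   `"clustered"` (k Gaussian clusters, mimicking regional groups of
#'   hot springs on distinct plates).
#' @param k_centers cluster count for clustered placement.
#' @param spread_deg Gaussian spread (degrees) around each cluster center.
#' @param seq_length sequence length in bases (>= 100).
#' @param mu expected substitutions per site per 1000 km (>= 0).
#' @param seed integer root seed; stage seeds are derived from it.
#' @return a list of class `ibd_params`.
#' @export
ibd_params <- function(n_sites = 9, placement = c("uniform_sphere",
                                                  "clustered"),
                       k_centers = 3, spread_deg = 1,
                       seq_length = 10000, mu = 0.005, seed = 1) {
  placement <- match.arg(placement)
  if (n_sites < 3) gv_stop("n_sites must be >= 3")
  if (seq_length < 100) gv_stop("seq_length must be >= 100")
  if (mu < 0) gv_stop("mu must be >= 0")
  if (placement == "clustered" && (k_centers < 1 || k_centers > n_sites))
    gv_stop("k_centers must be in [1, n_sites]")
  structure(list(n_sites = as.integer(n_sites), placement = placement,
                 k_centers = as.integer(k_centers),
                 spread_deg = spread_deg,
                 seq_length = as.integer(seq_length), mu = mu,
                 seed = as.integer(seed)),
            class = "ibd_params")
}

site_names <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate sampling sites
#'
#' Uniform placement draws longitude uniformly and latitude as
#' `asin(U(-1, 1))` so points are area-uniform on the sphere; each site
#' is then its own "plate" (fully allopatric sampling). Clustered
#' placement draws `k_centers` centers uniformly and scatters sites
#' around them with Gaussian spread; plate labels follow cluster
#' membership.
#'
#' @param params an [ibd_params()].
#' @return a [site_table()] with `n_sites` rows.
#' @export
simulate_sites <- function(params) {
  set.seed(derive_seed(params$seed, "sites"))
  n <- params$n_sites
  if (params$placement == "uniform_sphere") {
    lat <- asin(runif(n, -1, 1)) * 180 / pi
    lon <- runif(n, -180, 180)
    plate <- sprintf("P%02d", seq_len(n))
  } else {
    k <- params$k_centers
    clat <- asin(runif(k, -1, 1)) * 180 / pi
    clon <- runif(k, -180, 180)
    memb <- rep_len(seq_len(k), n)
    lat <- clat[memb] + rnorm(n, 0, params$spread_deg)
    lon <- clon[memb] + rnorm(n, 0, params$spread_deg)
    lat <- pmax(pmin(lat, 90), -90)
    plate <- sprintf("P%02d", memb)
  }
  site_table(name = site_names(n), lat = lat, lon = normalize_lon(lon),
             plate = plate)
}

#' Build a stepping-stone colonization tree over sites
#'
#' A random site is the root; the remaining sites are added in random
#' order, each attaching to the nearest (great-circle) already-colonized
#' site. Distance ties attach to the lexicographically smaller name.
#' Deterministic under a fixed seed.
#'
#' @param sites a [site_table()] whose rows all carry coordinates.
#' @param seed integer seed for root choice and addition order.
#' @return a list of class `colonization_tree`: `root`, `parent` (named
#'   character, `NA` for the root), `edge_km` (named numeric, great-circle
#'   length of the edge above each non-root site), `order` (colonization
#'   order).
#' @export
build_colonization_tree <- function(sites, seed = 1) {
  if (!inherits(sites, "site_table")) gv_stop("'sites' must be a site_table")
  if (nrow(sites) < 2) gv_stop("need >= 2 sites")
  missing <- sites_without_coords(sites)
  if (length(missing))
    gv_stop("sites lack coordinates: ", paste(missing, collapse = ", "))
  set.seed(derive_seed(seed, "tree"))
  nm <- sites$name
  n <- length(nm)
  ord <- sample.int(n)
  root <- nm[ord[1]]
  geo <- geographic_distance_matrix(sites)$values
  parent <- stats::setNames(rep(NA_character_, n), nm)
  edge_km <- stats::setNames(rep(NA_real_, n), nm)
  colonized <- root
  for (k in ord[-1]) {
    s <- nm[k]
    d <- geo[s, colonized]
    # ties go to the lexicographically smaller colonized name
    cand <- colonized[d == min(d)]
    p <- sort(cand)[1]
    parent[s] <- p
    edge_km[s] <- geo[s, p]
    colonized <- c(colonized, s)
  }
  structure(list(root = root, parent = parent, edge_km = edge_km,
                 order = nm[ord]),
            class = "colonization_tree")
}

#' Path length between two sites through the colonization tree, in km
#'
#' @param tree a `colonization_tree`.
#' @param a,b site names.
#' @return sum of edge lengths along the unique tree path.
#' @export
tree_path_km <- function(tree, a, b) {
  anc <- function(x) {
    path <- x
    while (!is.na(tree$parent[[x]])) {
      x <- tree$parent[[x]]
      path <- c(path, x)
    }
    path
  }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)[1]
  up <- function(path) {
    i <- match(common, path)
    if (i == 1) 0 else sum(tree$edge_km[path[seq_len(i - 1)]])
  }
  up(pa) + up(pb)
}

# all pairwise tree-path distances as a labeled matrix (km)
tree_path_matrix <- function(tree) {
  nm <- names(tree$parent)
  n <- length(nm)
  v <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v[i, j] <- v[j, i] <- tree_path_km(tree, nm[i], nm[j])
  }
  labeled_matrix(v, kind = "distance_km")
}

#' Evolve sequences along a colonization tree (Jukes-Cantor)
#'
#' The root receives a uniform-random ACGT sequence. Along each edge of
#' length g km, every position substitutes independently with probability
#' `p(g) = (3/4) * (1 - exp(-(4/3) * mu * g / 1000))`, to a base chosen
#' uniformly among the three alternatives. Edges are processed in a fixed
#' (name-sorted, root-down) order so output is bit-identical under a
#' fixed seed.
#'
#' @param tree a `colonization_tree`.
#' @param seq_length sequence length in bases.
#' @param mu expected substitutions per site per 1000 km.
#' @param seed integer seed.
#' @return a [sequence_set()], one sequence per site.
#' @export
evolve_sequences <- function(tree, seq_length, mu, seed = 1) {
  if (mu < 0) gv_stop("mu must be >= 0")
  set.seed(derive_seed(seed, "sequences"))
  bases <- c("A", "C", "G", "T")
  nm <- names(tree$parent)
  seqs <- vector("list", length(nm))
  names(seqs) <- nm
  seqs[[tree$root]] <- sample.int(4L, seq_length, replace = TRUE)
  # children in deterministic order: breadth-first from the root,
  # name-sorted within each level
  pending <- setdiff(nm, tree$root)
  frontier <- tree$root
  while (length(pending)) {
    nxt <- sort(pending[tree$parent[pending] %in% frontier])
    if (!length(nxt)) gv_stop("tree is not connected")
    for (s in nxt) {
      g <- tree$edge_km[[s]]
      p <- 0.75 * (1 - exp(-(4 / 3) * mu * g / 1000))
      parent_seq <- seqs[[tree$parent[[s]]]]
      child <- parent_seq
      hit <- which(runif(seq_length) < p)
      if (length(hit)) {
        # uniform among the three other bases: offset 1..3 mod 4
        child[hit] <- ((parent_seq[hit] - 1L +
                          sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      }
      seqs[[s]] <- child
    }
    frontier <- nxt
    pending <- setdiff(pending, nxt)
  }
  out <- vapply(seqs, function(x) paste(bases[x], collapse = ""), character(1))
  sequence_set(out)
}

#' Simulate a full isolation-by-distance dataset
#'
#' Runs [simulate_sites()], [build_colonization_tree()] and
#' [evolve_sequences()] with stage seeds derived from the root seed.
#'
#' @param params an [ibd_params()].
#' @return a list of class `ibd_dataset`: `sites`, `tree`, `sequences`,
#'   `params`.
#' @export
simulate_ibd <- function(params = ibd_params()) {
  sites <- simulate_sites(params)
  tree <- build_colonization_tree(sites, seed = params$seed)
  seqs <- evolve_sequences(tree, params$seq_length, params$mu,
                           seed = params$seed)
  structure(list(sites = sites, tree = tree, sequences = seqs,
                 params = params),
            class = "ibd_dataset")
}

#' Write an isolation-by-distance dataset to files
#'
#' Emits the site table (TSV), sequences (FASTA) and ground truth (JSON:
#' parameters, tree, seed) so every other module can be driven from
#' files.
#'
#' @param dataset an `ibd_dataset` from [simulate_ibd()].
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_ibd_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sites = file.path(dir, "sites.tsv"),
             fasta = file.path(dir, "sequences.fasta"),
             truth = file.path(dir, "truth.json"))
  write_site_table(dataset$sites, paths[["sites"]])
  write_fasta(dataset$sequences, paths[["fasta"]])
  truth <- list(params = unclass(dataset$params),
                root = dataset$tree$root,
                parent = as.list(dataset$tree$parent),
                edge_km = as.list(dataset$tree$edge_km))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}

#' Re-estimate the per-km substitution rate from simulated data
#'
#' For every pair of sites, the Jukes-Cantor-corrected divergence
#' ([jc69_distance()] of the observed proportion of differing sites) is
#' regressed through the origin on the colonization-tree path distance;
#' the slope, rescaled to per-1000-km units, estimates `mu`. Pairs at JC
#' saturation (p >= 0.75) are excluded with a warning; if all pairs are
#' saturated the estimate is undefined and an error is raised.
#'
#' @param seqs a [sequence_set()] generated on `tree`.
#' @param tree the `colonization_tree` the sequences evolved on.
#' @return estimated `mu` (substitutions per site per 1000 km).
#' @export
recover_mu <- function(seqs, tree) {
  nm <- names(tree$parent)
  if (!setequal(nm, names(seqs)))
    gv_stop("sequence names do not match tree sites")
  pmat <- p_distance_matrix(seqs)$values[nm, nm] / 100
  path <- tree_path_matrix(tree)$values
  ut <- upper.tri(pmat)
  p <- pmat[ut]
  g <- path[ut]
  sat <- p >= 0.75
  if (all(sat))
    gv_stop("all pairs are at JC69 saturation; mu cannot be estimated")
  if (any(sat))
    warning(sum(sat), " pair(s) at JC69 saturation excluded from the ",
            "mu regression", call. = FALSE)
  p <- p[!sat]; g <- g[!sat]
  d <- jc69_distance(p)
  if (sum(g^2) == 0) gv_stop("all tree paths have zero length")
  slope <- sum(d * g) / sum(g^2)   # least squares through the origin
  slope * 1000
}
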