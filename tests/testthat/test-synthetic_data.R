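test_that("simulated datasets are bit-identical under a fixed seed", {
  p <- ibd_params(n_sites = 6, seq_length = 200, mu = 0.01, seed = 77)
  d1 <- simulate_ibd(p)
  d2 <- simulate_ibd(p)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$tree, d2$tree)
  expect_identical(unclass(d1$sequences), unclass(d2$sequences))
  # a different seed moves the sites
  d3 <- simulate_ibd(ibd_params(n_sites = 6, seq_length = 200, mu = 0.01,
                                seed = 78))
  expect_false(identical(d1$sites$lat, d3$sites$lat))
})

test_that("clustered placement yields tight groups far apart", {
  p <- ibd_params(n_sites = 9, placement = "clustered", k_centers = 3,
                  spread_deg = 1, seq_length = 100, mu = 0, seed = 5)
  st <- simulate_sites(p)
  expect_equal(nrow(st), 9)
  expect_length(unique(st$plate), 3)
  g <- geographic_distance_matrix(st)$values
  same <- outer(st$plate, st$plate, "==")
  within <- g[same & upper.tri(g)]
  between <- g[!same & upper.tri(g)]
  expect_lt(max(within), min(between))
})

test_that("colonization trees attach each site to its nearest predecessor", {
  st2 <- site_table(name = c("A", "B"), lat = c(0, 0), lon = c(0, 10))
  tr2 <- build_colonization_tree(st2, seed = 1)
  e <- tr2$edge_km[!is.na(tr2$edge_km)]
  expect_length(e, 1)
  expect_equal(unname(e),
               great_circle_km(c(lat = 0, lon = 0), c(lat = 0, lon = 10)))

  # exact distance tie: two co-located candidates; lexicographically
  # smaller name wins whenever both are already colonized
  st3 <- site_table(name = c("A", "B", "C"), lat = c(0, 0, 0),
                    lon = c(10, 10, 40))
  found <- FALSE
  for (s in 1:50) {
    tr <- build_colonization_tree(st3, seed = s)
    if (tr$order[3] == "C") {
      expect_equal(unname(tr$parent[["C"]]), "A")
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # total length is bounded below by the minimum spanning tree
  p <- ibd_params(n_sites = 10, placement = "clustered", k_centers = 3,
                  spread_deg = 0.5, seq_length = 100, mu = 0, seed = 8)
  st <- simulate_sites(p)
  g <- geographic_distance_matrix(st)$values
  tr <- build_colonization_tree(st, seed = 8)
  total <- sum(tr$edge_km, na.rm = TRUE)
  expect_gte(total + 1e-9, oracle_mst_total(g))
  # clustered geometry: exactly k - 1 long between-cluster jumps
  expect_equal(sum(tr$edge_km > 500, na.rm = TRUE), 2)
})

test_that("edge substitution probability follows the JC69 closed form", {
  # two sites ~1000 km apart on the equator
  lon2 <- 1000 / 6371.0088 * 180 / pi
  st <- site_table(name = c("A", "B"), lat = c(0, 0), lon = c(0, lon2))
  tr <- build_colonization_tree(st, seed = 2)
  g <- unname(tr$edge_km[!is.na(tr$edge_km)])
  mu <- 0.01
  L <- 50000
  seqs <- evolve_sequences(tr, seq_length = L, mu = mu, seed = 3)
  p_obs <- p_distance_matrix(seqs)$values[1, 2] / 100
  p_exp <- 0.75 * (1 - exp(-(4 / 3) * mu * g / 1000))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # saturation: at extreme rates identity approaches 25%
  sat <- evolve_sequences(tr, seq_length = 100000, mu = 50, seed = 4)
  p_sat <- p_distance_matrix(sat)$values[1, 2] / 100
  expect_lt(abs(p_sat - 0.75), 0.005)

  # mu = 0 leaves every sequence identical to the root
  same <- evolve_sequences(tr, seq_length = 500, mu = 0, seed = 5)
  expect_identical(same[["A"]], same[["B"]])
})

test_that("recover_mu inverts the simulator", {
  p <- ibd_params(n_sites = 8, seq_length = 5000, mu = 0, seed = 21)
  ds <- simulate_ibd(p)
  expect_equal(recover_mu(ds$sequences, ds$tree), 0)

  # two sites: the slope equals d_JC / path exactly
  st <- site_table(name = c("A", "B"), lat = c(0, 0), lon = c(0, 20))
  tr <- build_colonization_tree(st, seed = 2)
  seqs <- evolve_sequences(tr, 2000, mu = 0.004, seed = 6)
  pd <- p_distance_matrix(seqs)$values[1, 2] / 100
  path <- unname(tr$edge_km[!is.na(tr$edge_km)])
  expect_equal(recover_mu(seqs, tr), jc69_distance(pd) / path * 1000,
               tolerance = 1e-12)

  # saturated pairs are excluded with a warning; all-saturated errors
  L <- 400
  s_root <- strrep("A", L)
  flip <- function(s, k) {
    pos <- seq_len(k)
    paste0(strrep("C", k), substr(s, k + 1, L))
  }
  st3 <- site_table(name = c("A", "B", "C"), lat = c(0, 1, 40),
                    lon = c(0, 1, 40))
  tr3 <- build_colonization_tree(st3, seed = 3)
  seqs3 <- sequence_set(c(A = s_root, B = flip(s_root, 40),
                          C = flip(s_root, 350)))
  expect_warning(est <- recover_mu(seqs3, tr3), "saturation")
  expect_true(is.finite(est))
  two <- sequence_set(c(A = s_root, B = flip(s_root, 350)))
  tr_two <- build_colonization_tree(st3[1:2, ], seed = 1)
  expect_error(suppressWarnings(recover_mu(two, tr_two)), "saturation")
})

test_that("datasets round-trip through files", {
  ds <- simulate_ibd(ibd_params(n_sites = 5, seq_length = 300, mu = 0.01,
                                seed = 55))
  dir <- tempfile()
  paths <- write_ibd_dataset(ds, dir)
  st <- read_site_table(paths[["sites"]])
  expect_equal(st$name, ds$sites$name)
  expect_equal(st$lat, ds$sites$lat, tolerance = 1e-9)
  seqs <- read_fasta(paths[["fasta"]])
  expect_identical(unclass(seqs)[names(ds$sequences)],
                   unclass(ds$sequences)[names(ds$sequences)])
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$params$mu, 0.01)
  expect_equal(truth$root, ds$tree$root)
})
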