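# End-to-end analysis pipeline: geographic distances -> genetic
# matrices -> Mantel / Spearman sympatry statistics -> threshold
# delimitation, with a machine-readable JSON report.

#' Build a pipeline configuration
#'
#' At least one genetic input is required: FASTA file(s) (identity
#' matrices are computed) and/or precomputed labeled similarity/distance
#' matrices (e.g. published DDH or 16S identity tables).
#'
#' @param site_table a [site_table()] or a TSV path for
#'   [read_site_table()].
#' @param fasta optional named character vector of FASTA paths; each
#'   becomes a genetic similarity matrix named after its element.
#' @param matrices optional named list; each element is a list with
#'   `path` (or `matrix`, a ready [labeled_matrix()]) and `kind`.
#' @param n_perm,alternative,seed permutation settings passed to
#'   [mantel()] and [spearman_sympatry()]. The seed is mandatory: every
#'   number in a report must be regenerable from inputs + seed.
#' @param thresholds named numeric vector of delimitation thresholds
#'   applied to every similarity matrix (defaults: `ddh_species` 70,
#'   `s16_species` 98.7, `s16_classic` 97).
#' @param linkage linkage for [cluster_at_threshold()].
#' @param out_dir optional output directory; when set, the report JSON
#'   and all computed matrices are written there.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(site_table, fasta = NULL, matrices = NULL,
                            n_perm = 9999,
                            alternative = "greater", seed,
                            thresholds = c(ddh_species = 70,
                                           s16_species = 98.7,
                                           s16_classic = 97),
                            linkage = "single",
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    gv_stop("a seed is required in pipeline mode")
  if (is.null(fasta) && (is.null(matrices) || !length(matrices)))
    gv_stop("at least one genetic input (fasta or matrices) is required")
  structure(list(site_table = site_table, fasta = fasta,
                 matrices = matrices, n_perm = n_perm,
                 alternative = alternative, seed = as.integer(seed),
                 thresholds = thresholds, linkage = linkage,
                 out_dir = out_dir),
            class = "pipeline_config")
}

file_hash <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

matrix_to_report <- function(m) {
  list(labels = m$labels, kind = m$kind, values = unname(m$values))
}

#' Run the full biogeography pipeline
#'
#' Stages: geographic distance matrix over the coordinate-bearing sites
#' (strains without coordinates are excluded from geographic analyses
#' with a recorded warning, but retained for delimitation); for each
#' genetic matrix, a Mantel test of genetic distance (similarities are
#' converted via 100 - S) against geographic distance; a Spearman rank
#' test of genetic similarity against tectonic-plate sympatry when plate
#' labels are present; threshold clustering of every similarity matrix
#' at each configured threshold. A degenerate matrix (zero variance)
#' aborts only the affected statistic, recording the error as a warning
#' in the report.
#'
#' @param config a [pipeline_config()].
#' @return the report, a list of class `pipeline_report`, invisibly when
#'   `out_dir` is set (the JSON and matrix TSVs are then written there).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    gv_stop("'config' must be a pipeline_config")
  warnings_log <- character()
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    warnings_log <<- c(warnings_log, msg)
  }

  # --- inputs ---------------------------------------------------------
  sites_path <- NULL
  sites <- config$site_table
  if (is.character(sites)) {
    sites_path <- sites
    sites <- read_site_table(sites)
  }
  genetic <- list()   # name -> labeled_matrix
  provenance <- list()
  if (!is.null(sites_path))
    provenance$site_table <- list(path = sites_path,
                                  md5 = file_hash(sites_path))
  for (nm in names(config$fasta)) {
    seqs <- read_fasta(config$fasta[[nm]])
    genetic[[nm]] <- identity_matrix(seqs)
    provenance[[nm]] <- list(path = config$fasta[[nm]],
                             md5 = file_hash(config$fasta[[nm]]))
  }
  for (nm in names(config$matrices)) {
    entry <- config$matrices[[nm]]
    if (!is.null(entry$matrix)) {
      genetic[[nm]] <- entry$matrix
    } else {
      genetic[[nm]] <- read_matrix(entry$path, entry$kind)
      provenance[[nm]] <- list(path = entry$path, md5 = file_hash(entry$path))
    }
  }

  # --- geographic stage ----------------------------------------------
  no_coord <- sites_without_coords(sites)
  geo <- NULL
  if (length(no_coord))
    note("excluded from geographic analyses (no coordinates): ",
         paste(no_coord, collapse = ", "))
  with_coords <- sites[!sites$name %in% no_coord, ]
  class(with_coords) <- class(sites)
  if (nrow(with_coords) >= 2) geo <- geographic_distance_matrix(with_coords)

  # --- sympatry matrix ------------------------------------------------
  sym <- NULL
  has_plate <- !is.na(sites$plate) & nzchar(sites$plate)
  if (any(has_plate)) {
    if (!all(has_plate))
      note("excluded from sympatry analysis (no plate label): ",
           paste(sites$name[!has_plate], collapse = ", "))
    plates <- stats::setNames(sites$plate[has_plate], sites$name[has_plate])
    if (length(unique(plates)) >= 2 && length(plates) >= 4) {
      sym <- sympatry_matrix(plates)
    } else {
      note("sympatry analysis skipped: need >= 4 labeled sites on >= 2 plates")
    }
  }

  # --- statistics and delimitation per genetic matrix -----------------
  try_stat <- function(what, expr) {
    tryCatch(expr, geovar_error = function(e) {
      note(what, ": ", conditionMessage(e))
      NULL
    })
  }
  mantel_results <- list()
  spearman_results <- list()
  clusters <- list()
  for (nm in names(genetic)) {
    gm <- genetic[[nm]]
    gdist <- if (gm$kind == "similarity_percent")
      similarity_to_distance(gm) else gm
    if (!is.null(geo)) {
      common <- intersect(gdist$labels, geo$labels)
      dropped <- setdiff(gdist$labels, common)
      if (length(dropped))
        note("Mantel (", nm, "): restricted to ", length(common),
             " coordinate-bearing strains; dropped: ",
             paste(dropped, collapse = ", "))
      if (length(common) >= 3) {
        mantel_results[[nm]] <- try_stat(paste0("Mantel (", nm, ")"), {
          mantel(subset_matrix(gdist, common), subset_matrix(geo, common),
                 n_perm = config$n_perm, alternative = config$alternative,
                 seed = derive_seed(config$seed, paste0("mantel:", nm)))
        })
      }
    }
    if (!is.null(sym)) {
      gsim <- if (gm$kind == "distance_percent")
        distance_to_similarity(gm) else gm
      common <- intersect(gsim$labels, sym$labels)
      if (length(common) >= 4) {
        dropped <- setdiff(gm$labels, common)
        if (length(dropped))
          note("Spearman (", nm, "): dropped (no plate): ",
               paste(dropped, collapse = ", "))
        spearman_results[[nm]] <- try_stat(paste0("Spearman (", nm, ")"), {
          spearman_sympatry(subset_matrix(gsim, common),
                            subset_matrix(sym, common),
                            n_perm = config$n_perm,
                            alternative = config$alternative,
                            seed = derive_seed(config$seed,
                                               paste0("spearman:", nm)))
        })
      }
    }
    if (gm$kind == "similarity_percent") {
      clusters[[nm]] <- lapply(config$thresholds, function(th)
        cluster_at_threshold(gm, th, linkage = config$linkage))
    }
  }

  report <- structure(list(
    tool = "geovar",
    version = as.character(utils::packageVersion("geovar")),
    seed = config$seed,
    inputs = provenance,
    settings = list(n_perm = config$n_perm,
                    alternative = config$alternative,
                    thresholds = as.list(config$thresholds),
                    linkage = config$linkage,
                    distance_convention = "similarities converted via 100 - S"),
    sites = list(names = sites$name, plates = as.list(
      stats::setNames(ifelse(is.na(sites$plate), "", sites$plate),
                      sites$name))),
    geographic_matrix = if (!is.null(geo)) matrix_to_report(geo),
    genetic_matrices = lapply(genetic, matrix_to_report),
    mantel = lapply(mantel_results, unclass),
    spearman = lapply(spearman_results, unclass),
    clusters = lapply(clusters, function(per_th)
      lapply(per_th, function(cs) list(partition = cs$partition,
                                       threshold = cs$threshold,
                                       linkage = cs$linkage))),
    warnings = as.list(warnings_log)
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    if (!is.null(geo))
      write_matrix(geo, file.path(config$out_dir, "geographic_km.tsv"))
    for (nm in names(genetic))
      write_matrix(genetic[[nm]],
                   file.path(config$out_dir, paste0(nm, "_matrix.tsv")))
  }
  invisible(report)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report's structure against the JSON schema in
#' `inst/schema/report-schema.json`: required top-level fields, types,
#' and symmetry of every embedded matrix.
#'
#' @param report a `pipeline_report` (or the list parsed back from its
#'   JSON).
#' @return `TRUE`, invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  required <- c("tool", "version", "seed", "inputs", "settings", "sites",
                "genetic_matrices", "mantel", "spearman", "clusters",
                "warnings")
  miss <- setdiff(required, names(report))
  if (length(miss))
    gv_stop("report is missing fields: ", paste(miss, collapse = ", "))
  if (!identical(as.character(report$tool), "geovar"))
    gv_stop("report 'tool' must be 'geovar'")
  check_mat <- function(entry, what) {
    vals <- entry$values
    if (!is.matrix(vals)) vals <- do.call(rbind, lapply(vals, unlist))
    if (nrow(vals) != ncol(vals))
      gv_stop(what, ": embedded matrix is not square")
    if (max(abs(vals - t(vals))) > 1e-9)
      gv_stop(what, ": embedded matrix is not symmetric")
  }
  if (!is.null(report$geographic_matrix))
    check_mat(report$geographic_matrix, "geographic_matrix")
  for (nm in names(report$genetic_matrices))
    check_mat(report$genetic_matrices[[nm]], nm)
  for (nm in names(report$mantel)) {
    mr <- report$mantel[[nm]]
    if (!is.null(mr) && abs(mr$r_m) > 1 + 1e-12)
      gv_stop("mantel ", nm, ": |r_m| > 1")
  }
  invisible(TRUE)
}
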