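# End-to-end orchestration from a single YAML configuration:
# (simulate ->) classify -> quantify -> compare -> report, with
# deterministic outputs under a fixed seed.

#' Read a pipeline run configuration
#'
#' The YAML file holds:
#' \preformatted{
#' seed: 1
#' reference:                  # either paths ...
#'   mature: mature.fa
#'   hairpin: hairpin.fa
#'   offsets: offsets.tsv      # optional
#' # ... or `synthetic: {n_groups: 8}` for a generated reference
#' classify: {max_tr: 8, max_ta: 8, min_match: 12,
#'            tail_dialect: mature_anchored, ambiguous_policy: drop}
#' thresholds: {rpm: 10}
#' denominator: all_reads      # or `assigned`
#' libraries:
#'   - {id: wt_1, genotype: wildtype, replicate: 1, role: in_vivo,
#'      path: wt_1.fa, format: collapsed}
#'   - {id: hen1_1, genotype: hen1, replicate: 1, role: in_vivo,
#'      simulate: hen1_like}   # preset name instead of a file
#' contrasts:
#'   - {a: wildtype, b: hen1, metrics: [p_TR, p_TRTA]}
#' }
#' Library roles are `in_vivo`, `IP_mock`, `IP_SDN1` or `IP_SDN1_D283A`;
#' for the IP assay roles a mock-subtracted TR/FL summary is produced.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Collects all structural problems at once; an empty character vector
#' means the configuration is runnable.
#'
#' @param config a `run_config` (or plain list).
#' @param check_files verify referenced files exist (default TRUE).
#' @return character vector of problems.
#' @export
validate_config <- function(config, check_files = TRUE) {
  probs <- character(0)
  add <- function(msg) probs <<- c(probs, msg)

  if (is.null(config$reference)) {
    add("no `reference` section")
  } else if (is.null(config$reference$synthetic)) {
    for (f in c("mature", "hairpin")) {
      if (is.null(config$reference[[f]])) {
        add(paste0("reference: missing `", f, "` path"))
      } else if (check_files && !file.exists(cfg_path(config,
                                                      config$reference[[f]]))) {
        add(paste0("reference file not found: ", config$reference[[f]]))
      }
    }
  }

  libs <- config$libraries
  if (is.null(libs) || !length(libs)) {
    add("no libraries defined")
    libs <- list()
  }
  ids <- vapply(libs, function(l) l$id %||% NA_character_, character(1))
  if (anyNA(ids)) add("library without an `id`")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) add(paste0("duplicate library id: ",
                              paste(dup, collapse = ", ")))
  roles <- c("in_vivo", "IP_mock", "IP_SDN1", "IP_SDN1_D283A")
  for (l in libs) {
    if (!is.null(l$role) && !l$role %in% roles) {
      add(paste0("library ", l$id, ": unknown role '", l$role, "'"))
    }
    if (!is.null(l$replicate) && l$replicate < 1) {
      add(paste0("library ", l$id, ": replicate index must be >= 1"))
    }
    if (is.null(l$path) && is.null(l$simulate)) {
      add(paste0("library ", l$id, ": needs `path` or `simulate`"))
    }
    if (!is.null(l$path) && check_files &&
        !file.exists(cfg_path(config, l$path))) {
      add(paste0("library file not found: ", l$path))
    }
    if (!is.null(l$simulate) &&
        !l$simulate %in% names(preset_profiles())) {
      add(paste0("library ", l$id, ": unknown preset '", l$simulate, "'"))
    }
  }
  genos <- unique(vapply(libs, function(l) l$genotype %||% NA_character_,
                         character(1)))
  for (ct in config$contrasts) {
    for (side in c("a", "b")) {
      if (!is.null(ct[[side]]) && !ct[[side]] %in% genos) {
        add(paste0("contrast references unknown genotype '", ct[[side]],
                   "'"))
      }
    }
  }
  probs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_path <- function(config, p) {
  if (is.null(config$.dir) || grepl("^/", p)) p else file.path(config$.dir, p)
}

#' Run the full pipeline
#'
#' Validates the configuration (aborting before any output on failure),
#' loads or simulates the reference and libraries, classifies, quantifies,
#' runs the configured contrasts, clusters libraries, applies
#' mock-subtraction to IP assay roles, and writes TSV outputs plus a log
#' and a file manifest into `out_dir`. Reruns with an identical
#' configuration and seed are byte-identical.
#'
#' @param config a `run_config` ([read_run_config()]) or path to one.
#' @param out_dir output directory (created; must be empty or absent).
#' @param seed overrides `config$seed` (default taken from the config,
#'   falling back to 1).
#' @return invisibly, a list with the in-memory results (`refset`, `libs`,
#'   `composition`, `contrasts`, `clustering`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  probs <- validate_config(config)
  if (length(probs)) {
    stop("configuration invalid:\n  - ", paste(probs, collapse = "\n  - "),
         call. = FALSE)
  }
  seed <- seed %||% config$seed %||% 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # reference
  if (!is.null(config$reference$synthetic)) {
    rs_args <- config$reference$synthetic
    refset <- synthetic_refset(n_groups = rs_args$n_groups %||% 8,
                               seed = derive_seed(seed, "reference"))
    log("reference: synthetic, ", nrow(refset$groups), " groups")
  } else {
    refset <- load_references(cfg_path(config, config$reference$mature),
                              cfg_path(config, config$reference$hairpin),
                              offsets = if (!is.null(config$reference$offsets))
                                cfg_path(config, config$reference$offsets))
    log("reference: ", nrow(refset$groups), " groups from FASTA")
  }

  params <- do.call(classify_params, config$classify %||% list())
  denominator <- config$denominator %||% "all_reads"
  rpm_threshold <- (config$thresholds %||% list())$rpm %||% 10

  # libraries: load or simulate, then classify
  meta <- dplyr::bind_rows(lapply(config$libraries, function(l) {
    tibble::tibble(library = l$id, genotype = l$genotype %||% NA_character_,
                   replicate = l$replicate %||% 1L,
                   role = l$role %||% "in_vivo")
  }))
  libs <- lapply(config$libraries, function(l) {
    if (!is.null(l$path)) {
      reads <- read_small_rna(cfg_path(config, l$path),
                              format = l$format %||% "auto")
    } else {
      prof <- preset_profiles()[[l$simulate]]
      if (!is.null(l$library_size)) {
        prof$library_size <- as.integer(l$library_size)
      }
      syn <- generate_library(prof, refset,
                              seed = derive_seed(seed, "library", l$id),
                              library_id = l$id)
      reads <- syn$reads
    }
    lib <- classify_library(reads, refset, params, library_id = l$id)
    s <- lib$stats
    log("library ", l$id, ": ", s$total_count, " reads, ", s$assigned,
        " assigned, ", s$unassigned, " unassigned (", s$length_filtered,
        " length-filtered), ", s$ambiguous_dropped, " ambiguous")
    lib
  })
  names(libs) <- meta$library

  calls_all <- dplyr::bind_rows(lapply(libs, `[[`, "calls"))
  stats_all <- dplyr::bind_rows(lapply(libs, `[[`, "stats"))
  comp <- dplyr::bind_rows(lapply(libs, compose, denominator = denominator))

  kept <- abundance_filter(comp, rpm_threshold)
  log("abundance filter (RPM > ", rpm_threshold, ", all libraries): ",
      length(kept), " group(s) kept")

  # contrasts on the abundance-filtered groups
  contrasts <- NULL
  for (ct in config$contrasts %||% list()) {
    res <- contrast_groups(comp[comp$group %in% kept, ], meta,
                           ct$a, ct$b,
                           metrics = unlist(ct$metrics) %||%
                             c("p_TR", "p_TRTA"))
    res$contrast <- paste0(ct$b, "_vs_", ct$a)
    contrasts <- dplyr::bind_rows(contrasts, res)
  }

  # binding fractions for IP libraries
  binding <- NULL
  ip_ids <- meta$library[meta$role != "in_vivo"]
  for (id in ip_ids) {
    b <- binding_fraction(libs[[id]])
    b$library <- id
    binding <- dplyr::bind_rows(binding, b)
  }

  # in vitro assay: pool replicates per role, subtract mock, TR/FL ratio
  assay <- NULL
  for (trt_role in c("IP_SDN1", "IP_SDN1_D283A")) {
    trt_ids <- meta$library[meta$role == trt_role]
    mock_ids <- meta$library[meta$role == "IP_mock"]
    if (!length(trt_ids) || !length(mock_ids)) next
    trt_comp <- compose(pool_replicates(libs[trt_ids]))
    mock_comp <- compose(pool_replicates(libs[mock_ids]))
    adj <- mock_subtract(trt_comp, mock_comp,
                         cols = c("n_FL", "n_TR", "n_TA", "n_TRTA"))
    adj$tr_fl_ratio <- tr_vs_fl_ratio(adj)
    adj$reaction <- trt_role
    assay <- dplyr::bind_rows(assay, adj)
  }

  clustering <- NULL
  if (nrow(meta) >= 2) {
    clustering <- cluster_libraries(species_rpm_table(libs,
                                                      denominator))
  }

  # outputs
  wtsv <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
    }
  }
  wtsv(calls_all, "calls.tsv")
  wtsv(stats_all, "library_stats.tsv")
  wtsv(comp, "composition.tsv")
  wtsv(matrix_table(libs, params$max_tr, params$max_ta), "matrices.tsv")
  writeLines(kept, file.path(out_dir, "abundant_groups.txt"))
  wtsv(contrasts, "contrasts.tsv")
  wtsv(binding, "binding_fractions.tsv")
  wtsv(assay, "sdn1_assay.tsv")
  if (!is.null(clustering)) {
    readr::write_tsv(tibble::as_tibble(clustering$dist, rownames = "library"),
                     file.path(out_dir, "distances.tsv"), progress = FALSE)
    writeLines(clustering$newick, file.path(out_dir, "tree.nwk"))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))

  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- tibble::tibble(file = files,
                             md5 = unname(tools::md5sum(
                               file.path(out_dir, files))),
                             seed = seed)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)

  invisible(list(refset = refset, libs = libs, composition = comp,
                 contrasts = contrasts, clustering = clustering,
                 assay = assay, out_dir = out_dir))
}
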