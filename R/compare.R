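# Cross-library procedures: mock/catalytic-mutant subtraction for in vitro
# exonuclease assays, TR/FL ratios, replicate pooling (at the count level,
# never mean-of-ratios), two-group significance tests with star annotation,
# and sample clustering on log-transformed RPM.

#' Subtract a mock/control signal from a treatment table
#'
#' Entrywise `treatment - control`, floored at 0, over the numeric columns
#' shared by the two tables (or `cols`). Rows are aligned on `group` (plus
#' any other shared key columns in `by`). A group present only in the
#' control is kept with all-zero adjusted values (treatment treated as 0);
#' a message notes such groups.
#'
#' @param treatment,control tibbles with a `group` column and numeric
#'   value columns on the same scale (proportions or RPM).
#' @param cols value columns to subtract; default: all shared numeric
#'   columns.
#' @param by key column(s), default `"group"`.
#' @return adjusted tibble with the same value columns.
#' @export
mock_subtract <- function(treatment, control, cols = NULL, by = "group") {
  treatment <- tibble::as_tibble(treatment)
  control <- tibble::as_tibble(control)
  if (is.null(cols)) {
    shared <- intersect(names(treatment), names(control))
    cols <- shared[vapply(treatment[shared], is.numeric, logical(1))]
    cols <- setdiff(cols, by)
  }
  merged <- dplyr::full_join(treatment[, c(by, cols)],
                             control[, c(by, cols)],
                             by = by, suffix = c(".t", ".c"))
  only_control <- merged[[by[1]]][rowSums(is.na(
    merged[paste0(cols, ".t")])) > 0]
  if (length(only_control)) {
    message("group(s) absent from treatment, adjusted to 0: ",
            paste(only_control, collapse = ", "))
  }
  out <- merged[, by, drop = FALSE]
  for (cl in cols) {
    t_v <- merged[[paste0(cl, ".t")]]
    c_v <- merged[[paste0(cl, ".c")]]
    t_v[is.na(t_v)] <- 0
    c_v[is.na(c_v)] <- 0
    out[[cl]] <- pmax(t_v - c_v, 0)
  }
  tibble::as_tibble(out)
}

#' Ratio of TR-only to FL species
#'
#' Used after mock subtraction to compare enzymatic and catalytic-mutant
#' reactions. Groups with no FL signal get `NA` (and a message).
#'
#' @param comp rows with `n_TR` and `n_FL` (possibly subtracted values).
#' @return numeric vector `n_TR / n_FL`, `NA` where `n_FL == 0`.
#' @export
tr_vs_fl_ratio <- function(comp) {
  zero <- comp$n_FL == 0
  if (any(zero)) {
    who <- if ("group" %in% names(comp)) comp$group[zero] else which(zero)
    message("no FL signal, ratio undefined for: ", paste(who, collapse = ", "))
  }
  ifelse(zero, NA_real_, comp$n_TR / comp$n_FL)
}

#' Pool replicate libraries at the count level
#'
#' Sums call counts across replicates before any ratio is computed
#' (pool-then-ratio, not mean-of-ratios): the convention when per-replicate
#' signal is too sparse.
#'
#' @param calls_list list of calls tibbles (or `isotrim_library` objects).
#' @param library_id label for the pooled calls.
#' @return pooled calls tibble.
#' @export
pool_replicates <- function(calls_list, library_id = "pooled") {
  stopifnot(length(calls_list) >= 1)
  calls <- dplyr::bind_rows(lapply(calls_list, function(x) {
    if (inherits(x, "isotrim_library")) x$calls else tibble::as_tibble(x)
  }))
  calls |>
    dplyr::group_by(.data$group, .data$tr, .data$tail_seq, .data$ta,
                    .data$category) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(library = library_id, .before = 1)
}

#' Two-group test on replicate values with star annotation
#'
#' Two-sided t-test on raw per-replicate values (Welch by default; pooled
#' variance with `var_equal = TRUE`), with stars at 0.05 / 0.01 / 0.001.
#' With fewer than two values in either group the p-value is missing and
#' stars empty. Two degenerate cases fall outside `stats::t.test`: if both
#' groups are constant with equal means, p = 1; if both are constant with
#' different means, p = 0.
#'
#' @param values_a,values_b numeric vectors of per-replicate values
#'   (proportions or ratios).
#' @param group_name,metric_name labels carried into the result.
#' @param var_equal use the pooled-variance Student test (default FALSE).
#' @return one-row tibble: `group`, `metric`, `mean_A`, `mean_B`, `sd_A`,
#'   `sd_B`, `n_A`, `n_B`, `p_value`, `stars`, `direction` (sign of
#'   `mean_B - mean_A`).
#' @export
two_group_test <- function(values_a, values_b, group_name = NA_character_,
                           metric_name = NA_character_, var_equal = FALSE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  n_a <- length(values_a)
  n_b <- length(values_b)
  m_a <- if (n_a) mean(values_a) else NA_real_
  m_b <- if (n_b) mean(values_b) else NA_real_
  s_a <- if (n_a >= 2) stats::sd(values_a) else NA_real_
  s_b <- if (n_b >= 2) stats::sd(values_b) else NA_real_

  p <- NA_real_
  if (n_a >= 2 && n_b >= 2) {
    if (isTRUE(all.equal(s_a, 0)) && isTRUE(all.equal(s_b, 0))) {
      p <- if (isTRUE(all.equal(m_a, m_b))) 1 else 0
    } else {
      p <- stats::t.test(values_a, values_b, var.equal = var_equal)$p.value
    }
  }
  tibble::tibble(group = group_name, metric = metric_name,
                 mean_A = m_a, mean_B = m_b, sd_A = s_a, sd_B = s_b,
                 n_A = n_a, n_B = n_b, p_value = p,
                 stars = star_for_p(p),
                 direction = sign(m_b - m_a))
}

#' Test the summed truncation signal (TR-only + TR+TA)
#'
#' Applies [two_group_test()] to the per-replicate sum `p_TR + p_TRTA`
#' (identical to the per-replicate truncation ratio): a reduction in total
#' 3' truncation can be significant even when neither component is.
#'
#' @param comp_a,comp_b per-replicate composition rows for one group
#'   (columns `p_TR`, `p_TRTA`).
#' @inheritParams two_group_test
#' @return one-row tibble as [two_group_test()], metric
#'   `"truncation_ratio"` unless overridden.
#' @export
sum_truncation_test <- function(comp_a, comp_b, group_name = NA_character_,
                                metric_name = "truncation_ratio",
                                var_equal = FALSE) {
  two_group_test(comp_a$p_TR + comp_a$p_TRTA,
                 comp_b$p_TR + comp_b$p_TRTA,
                 group_name = group_name, metric_name = metric_name,
                 var_equal = var_equal)
}

#' Contrast two genotypes across groups and metrics
#'
#' Runs [two_group_test()] per group for each requested metric, taking
#' per-replicate values from a composition table annotated with library
#' metadata. Groups must be present in every replicate of both genotypes
#' to be tested.
#'
#' @param comp composition rows for all libraries ([compose()] output,
#'   bound together).
#' @param meta tibble mapping `library` to `genotype`.
#' @param genotype_a,genotype_b labels to contrast (B vs A).
#' @param metrics columns of `comp` (or `"truncation_ratio"` /
#'   `"tronly_ratio"`, computed on the fly) to test.
#' @param adjust add a Benjamini-Hochberg `p_adj` column per metric
#'   (default FALSE; the convention is raw p-values with stars).
#' @param var_equal see [two_group_test()].
#' @return tibble of contrast rows.
#' @export
contrast_groups <- function(comp, meta, genotype_a, genotype_b,
                            metrics = c("p_TR", "p_TRTA"),
                            adjust = FALSE, var_equal = FALSE) {
  comp <- dplyr::left_join(comp, meta[, c("library", "genotype")],
                           by = "library")
  comp$truncation_ratio <- truncation_ratio(comp)
  comp$tronly_ratio <- tronly_ratio(comp)
  a <- comp[comp$genotype == genotype_a, ]
  b <- comp[comp$genotype == genotype_b, ]
  groups <- intersect(unique(a$group), unique(b$group))
  out <- dplyr::bind_rows(lapply(groups, function(gp) {
    dplyr::bind_rows(lapply(metrics, function(mt) {
      two_group_test(a[[mt]][a$group == gp], b[[mt]][b$group == gp],
                     group_name = gp, metric_name = mt,
                     var_equal = var_equal)
    }))
  }))
  if (adjust && nrow(out)) {
    out <- out |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  out
}

#' Species-level RPM table across libraries
#'
#' One row per isoform species, one column per library, holding RPM.
#' Library distances computed on these profiles see composition shifts
#' (truncation/tailing changes) as well as abundance changes, which
#' group-total RPM alone cannot. At the default `"category"` resolution a
#' species is a (group, category) pair — four well-populated cells per
#' group; `"isoform"` resolves the full (group, tr, ta) grid, whose many
#' low-count cells add sampling noise to distances in small libraries.
#'
#' @param libs list of `isotrim_library` objects.
#' @param denominator passed to the RPM computation: `"all_reads"`
#'   (default) uses each library's filtered read total, `"assigned"` the
#'   assigned total.
#' @param level `"category"` (default) or `"isoform"`.
#' @return numeric matrix, species x libraries.
#' @export
species_rpm_table <- function(libs, denominator = c("all_reads",
                                                    "assigned"),
                              level = c("category", "isoform")) {
  denominator <- match.arg(denominator)
  level <- match.arg(level)
  long <- dplyr::bind_rows(lapply(libs, function(lib) {
    tot <- if (denominator == "all_reads") {
      lib$stats$total_count - lib$stats$length_filtered
    } else {
      lib$stats$assigned
    }
    agg <- if (level == "category") {
      lib$calls |>
        dplyr::group_by(.data$group, .data$category) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
        dplyr::mutate(species = paste(.data$group, .data$category,
                                      sep = ":"))
    } else {
      lib$calls |>
        dplyr::group_by(.data$group, .data$tr, .data$ta) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
        dplyr::mutate(species = paste(.data$group, .data$tr, .data$ta,
                                      sep = ":"))
    }
    agg |>
      dplyr::mutate(library = lib$library_id,
                    rpm = rpm(.data$count, tot))
  }))
  wide <- long |>
    dplyr::select("species", "library", "rpm") |>
    tidyr::pivot_wider(names_from = "library", values_from = "rpm",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$species
  m
}

#' Cluster libraries on log-transformed RPM
#'
#' Sample-to-sample Euclidean distances on `log2(RPM + 1)` profiles,
#' agglomerated hierarchically (average linkage by default), as used for
#' replicate-concordance checks.
#'
#' @param rpm_table groups x libraries numeric matrix of RPM values, or a
#'   long tibble with columns `library`, `group`, `rpm_total`.
#' @param linkage one of `"average"`, `"single"`, `"complete"`, `"ward"`.
#' @return list of class `library_clustering`: `dist` (matrix), `hclust`,
#'   `newick` (tree serialization).
#' @export
cluster_libraries <- function(rpm_table,
                              linkage = c("average", "single", "complete",
                                          "ward")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(rpm_table)) {
    wide <- rpm_table |>
      dplyr::select("library", "group", "rpm_total") |>
      tidyr::pivot_wider(names_from = "library",
                         values_from = "rpm_total", values_fill = 0)
    rpm_table <- as.matrix(wide[, -1, drop = FALSE])
    rownames(rpm_table) <- wide$group
  }
  if (ncol(rpm_table) < 2) stop("need at least 2 libraries", call. = FALSE)
  lg <- log2(rpm_table + 1)
  d <- stats::dist(t(lg), method = "euclidean")
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else
    linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(dist = as.matrix(d), hclust = hc, newick = newick),
            class = "library_clustering")
}

#' @export
print.library_clustering <- function(x, ...) {
  cat("<library_clustering> ", ncol(x$dist), " libraries, linkage: ",
      x$hclust$method, "\n", x$newick, "\n", sep = "")
  invisible(x)
}
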