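# Normalised quantities built from aggregated isoform calls: RPM,
# four-category compositions, truncation ratios, abundance filters, AGO-IP
# binding fractions, truncation-tailing matrices, and plain count ->
# percentage tables.

#' Reads per million
#'
#' @param count read count(s).
#' @param library_total library denominator (> 0); by convention the number
#'   of reads passing the length filter (assigned + unassigned), but a
#'   miRNA-assigned total may be used instead (see [compose()]).
#' @return `count / library_total * 1e6`.
#' @export
rpm <- function(count, library_total) {
  if (any(library_total == 0)) {
    stop("library_total must be > 0", call. = FALSE)
  }
  count / library_total * 1e6
}

#' Per-group four-category composition of one library
#'
#' For each miRNA group, the FL / TR-only / TA-only / TR+TA counts, their
#' proportions of the group total, and the group's RPM. Groups with zero
#' reads simply do not appear (no 0/0 rows).
#'
#' @param x an `isotrim_library` from [classify_library()], or a calls
#'   tibble (columns `group`, `category`, `count`, optionally `library`).
#' @param library_total RPM denominator; defaults to the library's total
#'   filtered read count when `x` is an `isotrim_library`
#'   (`denominator = "all_reads"`) or to the assigned total otherwise.
#' @param denominator `"all_reads"` (default) or `"assigned"`.
#' @return tibble with columns `library`, `group`, `n_FL`, `n_TR`, `n_TA`,
#'   `n_TRTA`, `total`, `rpm_total`, `p_FL`, `p_TR`, `p_TA`, `p_TRTA`.
#' @export
compose <- function(x, library_total = NULL,
                    denominator = c("all_reads", "assigned")) {
  denominator <- match.arg(denominator)
  if (inherits(x, "isotrim_library")) {
    calls <- x$calls
    if (is.null(library_total)) {
      library_total <- if (denominator == "all_reads") {
        x$stats$total_count - x$stats$length_filtered
      } else {
        x$stats$assigned
      }
    }
  } else {
    calls <- tibble::as_tibble(x)
    if (!"library" %in% names(calls)) calls$library <- "library"
    if (is.null(library_total)) library_total <- sum(calls$count)
  }
  if (nrow(calls) == 0) {
    return(tibble::tibble(library = character(), group = character(),
                          n_FL = numeric(), n_TR = numeric(),
                          n_TA = numeric(), n_TRTA = numeric(),
                          total = numeric(), rpm_total = numeric(),
                          p_FL = numeric(), p_TR = numeric(),
                          p_TA = numeric(), p_TRTA = numeric()))
  }
  calls |>
    dplyr::group_by(.data$library, .data$group) |>
    dplyr::summarise(
      n_FL = sum(.data$count[.data$category == "FL"]),
      n_TR = sum(.data$count[.data$category == "TR_ONLY"]),
      n_TA = sum(.data$count[.data$category == "TA_ONLY"]),
      n_TRTA = sum(.data$count[.data$category == "TR_TA"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      total = .data$n_FL + .data$n_TR + .data$n_TA + .data$n_TRTA,
      rpm_total = rpm(.data$total, library_total),
      p_FL = .data$n_FL / .data$total,
      p_TR = .data$n_TR / .data$total,
      p_TA = .data$n_TA / .data$total,
      p_TRTA = .data$n_TRTA / .data$total
    ) |>
    dplyr::filter(.data$total > 0)
}

#' Truncation ratio: proportion of truncated species (TR-only + TR+TA)
#'
#' @param comp composition rows from [compose()].
#' @return numeric vector, `(n_TR + n_TRTA) / total`; `NA` where
#'   `total == 0`.
#' @export
truncation_ratio <- function(comp) {
  ifelse(comp$total > 0, (comp$n_TR + comp$n_TRTA) / comp$total, NA_real_)
}

#' TR-only ratio: proportion of truncated-but-untailed species
#'
#' @inheritParams truncation_ratio
#' @return numeric vector, `n_TR / total`; `NA` where `total == 0`.
#' @export
tronly_ratio <- function(comp) {
  ifelse(comp$total > 0, comp$n_TR / comp$total, NA_real_)
}

#' Abundance filter across libraries
#'
#' Keeps groups whose RPM exceeds the threshold in every library
#' (`mode = "all_libraries"`, the convention for presenting "abundant"
#' miRNAs) or in at least one (`mode = "any_library"`). A group missing
#' from a library counts as 0 RPM there.
#'
#' @param comp composition rows (several libraries bound together).
#' @param threshold_rpm RPM cutoff, exclusive (default 10).
#' @param mode `"all_libraries"` (default) or `"any_library"`.
#' @return character vector of retained group names (sorted).
#' @export
abundance_filter <- function(comp, threshold_rpm = 10,
                             mode = c("all_libraries", "any_library")) {
  mode <- match.arg(mode)
  libs <- unique(comp$library)
  wide <- comp |>
    dplyr::select("library", "group", "rpm_total") |>
    tidyr::pivot_wider(names_from = "library", values_from = "rpm_total",
                       values_fill = 0)
  ok <- apply(as.matrix(wide[, libs, drop = FALSE]), 1, function(v) {
    if (mode == "all_libraries") all(v > threshold_rpm)
    else any(v > threshold_rpm)
  })
  sort(wide$group[ok])
}

#' AGO-IP binding fraction
#'
#' Quantifies the binding of an Argonaute to each miRNA as the percentage
#' of reads for that miRNA among all miRNA-assigned reads in the IP
#' library.
#'
#' @param x an `isotrim_library` or calls tibble with `group`, `count`.
#' @return tibble with `group` and `percent` (sums to 100).
#' @export
binding_fraction <- function(x) {
  calls <- if (inherits(x, "isotrim_library")) x$calls else
    tibble::as_tibble(x)
  tot <- sum(calls$count)
  if (tot == 0) stop("no assigned reads in library", call. = FALSE)
  calls |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(percent = sum(.data$count) / tot * 100,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$percent))
}

#' Truncation-tailing matrix for one group
#'
#' The grid of isoform proportions indexed by nucleotides truncated (rows)
#' and nucleotides added (columns) — the quantity drawn as circle-size
#' matrices for miR165/6.
#'
#' @param x an `isotrim_library` or calls tibble.
#' @param group group name (may be omitted when the calls hold one group).
#' @param max_tr,max_ta grid extents (defaults 8), giving a
#'   `(max_tr + 1) x (max_ta + 1)` matrix with dimnames `0..max_tr` /
#'   `0..max_ta`.
#' @return numeric matrix of proportions summing to 1.
#' @export
build_matrix <- function(x, group = NULL, max_tr = 8, max_ta = 8) {
  calls <- if (inherits(x, "isotrim_library")) x$calls else
    tibble::as_tibble(x)
  if (!is.null(group)) calls <- calls[calls$group == group, ]
  if (nrow(calls) == 0 || sum(calls$count) == 0) {
    stop("no reads for the requested group", call. = FALSE)
  }
  m <- matrix(0, nrow = max_tr + 1, ncol = max_ta + 1,
              dimnames = list(tr = 0:max_tr, ta = 0:max_ta))
  agg <- calls |>
    dplyr::group_by(.data$tr, .data$ta) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  if (any(agg$tr > max_tr | agg$ta > max_ta)) {
    stop("calls exceed the requested grid extents", call. = FALSE)
  }
  m[cbind(agg$tr + 1, agg$ta + 1)] <- agg$count / sum(agg$count)
  m
}

#' Long-form truncation-tailing matrix across libraries/groups
#'
#' @param libs list of `isotrim_library` objects.
#' @param max_tr,max_ta grid extents (defaults 8).
#' @return tibble `library`, `group`, `tr`, `ta`, `proportion`.
#' @export
matrix_table <- function(libs, max_tr = 8, max_ta = 8) {
  dplyr::bind_rows(lapply(libs, function(lib) {
    dplyr::bind_rows(lapply(unique(lib$calls$group), function(gp) {
      m <- build_matrix(lib, gp, max_tr, max_ta)
      tibble::tibble(library = lib$library_id, group = gp,
                     tr = rep(0:max_tr, times = max_ta + 1),
                     ta = rep(0:max_ta, each = max_tr + 1),
                     proportion = as.vector(m))
    }))
  }))
}

#' Count -> percentage table with half-up display rounding
#'
#' Turns raw category counts (e.g. phenotype tallies of transformant
#' populations) into percentages of their sum, rounded half-up to one
#' decimal as printed tables conventionally are.
#'
#' @param counts non-negative numeric vector (sum > 0), optionally named.
#' @return list with `percent` (rounded, same names) and `total`.
#' @export
#' @examples
#' percent_table(c(WT_like = 9, Weak = 4, Moderate = 5, Strong = 17))
percent_table <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("counts sum to zero", call. = FALSE)
  list(percent = round_half_up(100 * counts / total, 1), total = total)
}
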