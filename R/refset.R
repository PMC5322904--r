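# Reference handling: mature + hairpin FASTA in the miRBase dialect, with
# identical mature sequences collapsed into named groups (miR165a + miR165b
# -> "miR165ab"). Each group carries the hairpin context 3' of the mature
# end, needed to distinguish templated extension from true tailing.

#' Load a miRNA reference set
#'
#' Reads mature and hairpin FASTA files (miRBase-style headers: the first
#' whitespace-delimited token is the record id), locates every mature
#' sequence inside its hairpin, and collapses identical mature sequences
#' into groups. The group name is the shared name stem plus the sorted,
#' concatenated one-letter suffixes (e.g. `miR165a` + `miR165b` ->
#' `"miR165ab"`); an override table can replace computed names.
#'
#' A mature record is paired with the hairpin of the same id unless the
#' offsets table says otherwise. If a mature sequence occurs at more than
#' one position in its hairpin the offsets table is required, because the
#' downstream templated context would be ambiguous.
#'
#' @param mature_fasta path to the mature-sequence FASTA.
#' @param hairpin_fasta path to the hairpin/precursor FASTA.
#' @param offsets optional path to a TSV with columns `mature_name`,
#'   `hairpin_name`, `offset_0based` (0-based start of the mature within the
#'   hairpin).
#' @param group_names optional named character vector overriding computed
#'   group names; names are member ids joined by `"+"` in sorted order.
#' @return an object of class `mirna_refset`: a list with element `groups`,
#'   a tibble with one row per collapsed group (columns `group_name`,
#'   `members` (list), `mature`, `mature_len`, `hairpin_name`, `hairpin`,
#'   `mature_offset` (0-based), `downstream`).
#' @export
#' @examples
#' mat <- tempfile(fileext = ".fa"); hp <- tempfile(fileext = ".fa")
#' writeLines(c(">miR900a", "AUCGAUCGAUCGAUCGAUCGA",
#'              ">miR900b", "AUCGAUCGAUCGAUCGAUCGA"), mat)
#' writeLines(c(">miR900a", "AUCGAUCGAUCGAUCGAUCGAGGGCCC",
#'              ">miR900b", "CCAUCGAUCGAUCGAUCGAUCGAGGG"), hp)
#' rs <- load_references(mat, hp)
#' rs$groups$group_name
load_references <- function(mature_fasta, hairpin_fasta, offsets = NULL,
                            group_names = NULL) {
  mat <- read_fasta_named(mature_fasta)
  hp <- read_fasta_named(hairpin_fasta)

  off <- NULL
  if (!is.null(offsets) && !identical(offsets, "")) {
    off <- readr::read_tsv(offsets, show_col_types = FALSE,
                           progress = FALSE)
    need <- c("mature_name", "hairpin_name", "offset_0based")
    if (!all(need %in% names(off))) {
      stop("offsets table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }

  rows <- lapply(names(mat), function(id) {
    mseq <- mat[[id]]
    if (nchar(mseq) < 15) {
      stop("mature record '", id, "' is implausibly short (",
           nchar(mseq), " nt)", call. = FALSE)
    }
    if (!is.null(off) && id %in% off$mature_name) {
      o <- off[off$mature_name == id, , drop = FALSE][1, ]
      hname <- o$hairpin_name
      if (!hname %in% names(hp)) {
        stop("offsets table names unknown hairpin '", hname,
             "' for mature '", id, "'", call. = FALSE)
      }
      pos0 <- as.integer(o$offset_0based)
      hseq <- hp[[hname]]
      if (substr(hseq, pos0 + 1, pos0 + nchar(mseq)) != mseq) {
        stop("mature '", id, "' does not match hairpin '", hname,
             "' at offset ", pos0, call. = FALSE)
      }
    } else {
      if (!id %in% names(hp)) {
        stop("mature '", id, "' has no same-named hairpin and no offsets ",
             "table entry", call. = FALSE)
      }
      hname <- id
      hseq <- hp[[hname]]
      hits <- gregexpr(mseq, hseq, fixed = TRUE)[[1]]
      if (identical(as.integer(hits), -1L)) {
        stop("mature '", id, "' not found in hairpin '", hname, "'",
             call. = FALSE)
      }
      if (length(hits) > 1) {
        stop("mature '", id, "' occurs at multiple positions in hairpin '",
             hname, "'; an offsets table is required", call. = FALSE)
      }
      pos0 <- as.integer(hits[1]) - 1L
    }
    tibble::tibble(member = id, mature = mseq, hairpin_name = hname,
                   mature_offset = pos0)
  })
  rows <- dplyr::bind_rows(rows)

  groups <- rows |>
    dplyr::group_by(.data$mature) |>
    dplyr::summarise(
      members = list(sort(.data$member)),
      # representative hairpin context: first member in sorted order
      hairpin_name = .data$hairpin_name[order(.data$member)][1],
      mature_offset = .data$mature_offset[order(.data$member)][1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      group_name = vapply(.data$members, make_group_name, character(1)),
      mature_len = nchar(.data$mature),
      hairpin = unname(unlist(hp[.data$hairpin_name])),
      downstream = substr(.data$hairpin,
                          .data$mature_offset + .data$mature_len + 1,
                          nchar(.data$hairpin))
    )

  if (!is.null(group_names)) {
    key <- vapply(groups$members, function(m) paste(m, collapse = "+"),
                  character(1))
    hit <- key %in% names(group_names)
    groups$group_name[hit] <- unname(group_names[key[hit]])
  }
  if (anyDuplicated(groups$group_name)) {
    dup <- unique(groups$group_name[duplicated(groups$group_name)])
    warning("computed group names collide (", paste(dup, collapse = ", "),
            "); made unique with numeric suffixes")
    groups$group_name <- make.unique(groups$group_name, sep = ".")
  }

  groups <- groups |>
    dplyr::arrange(.data$group_name) |>
    dplyr::select("group_name", "members", "mature", "mature_len",
                  "hairpin_name", "hairpin", "mature_offset", "downstream")

  structure(list(groups = groups), class = "mirna_refset")
}

# FASTA -> named character vector of normalized RNA sequences.
# Duplicate ids are a hard error.
read_fasta_named <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_rna(as.character(ss), ids = ids)
  stats::setNames(seqs, ids)
}

# "miR165a"+"miR165b" -> "miR165ab"; falls back to joining full names with
# "/" when the members do not share a stem + one-letter-suffix pattern.
make_group_name <- function(members) {
  members <- sort(members)
  if (length(members) == 1) return(members)
  stems <- sub("[a-z]$", "", members)
  sufs <- ifelse(grepl("[a-z]$", members),
                 substr(members, nchar(members), nchar(members)), "")
  if (length(unique(stems)) == 1 && all(sufs != "")) {
    paste0(stems[1], paste(sort(sufs), collapse = ""))
  } else {
    paste(members, collapse = "/")
  }
}

#' Templated context downstream of the mature 3' end
#'
#' Returns up to `n` hairpin bases immediately 3' of the mature sequence
#' (fewer if the hairpin ends first; empty string for `n = 0`).
#'
#' @param ref a single-group row of `refset$groups` (or a list with a
#'   `downstream` element).
#' @param n number of bases requested, >= 0.
#' @return RNA string of length <= n.
#' @export
downstream_context <- function(ref, n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  substr(ref$downstream, 1, n)
}

#' Extract one reference group by name
#'
#' @param refset a `mirna_refset`.
#' @param group group name.
#' @return one-row tibble for the group.
#' @export
get_ref <- function(refset, group) {
  i <- match(group, refset$groups$group_name)
  if (is.na(i)) stop("unknown group '", group, "'", call. = FALSE)
  refset$groups[i, ]
}

#' Write a reference set back to FASTA + offsets
#'
#' Emits one mature record per member locus, the (representative) hairpins,
#' and an offsets table mapping every member to its group's hairpin, such
#' that `load_references()` on the written files reproduces the set.
#'
#' @param refset a `mirna_refset`.
#' @param mature_fasta,hairpin_fasta,offsets output paths.
#' @return invisibly, the refset.
#' @export
write_references <- function(refset, mature_fasta, hairpin_fasta, offsets) {
  g <- refset$groups
  mat_lines <- unlist(lapply(seq_len(nrow(g)), function(i) {
    unlist(lapply(g$members[[i]], function(m) c(paste0(">", m), g$mature[i])))
  }))
  writeLines(mat_lines, mature_fasta)
  hp <- g |> dplyr::distinct(.data$hairpin_name, .data$hairpin)
  writeLines(as.vector(rbind(paste0(">", hp$hairpin_name), hp$hairpin)),
             hairpin_fasta)
  off <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    tibble::tibble(mature_name = g$members[[i]],
                   hairpin_name = g$hairpin_name[i],
                   offset_0based = g$mature_offset[i])
  }))
  readr::write_tsv(off, offsets, progress = FALSE)
  invisible(refset)
}

#' @export
print.mirna_refset <- function(x, ...) {
  cat("<mirna_refset> ", nrow(x$groups), " groups (",
      sum(lengths(x$groups$members)), " loci)\n", sep = "")
  print(dplyr::select(x$groups, "group_name", "mature_len", "hairpin_name"),
        n = 10)
  invisible(x)
}
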