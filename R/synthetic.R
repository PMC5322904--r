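# Ground-truth synthetic libraries. Reads are built as
# mature[1 : L - tr] + tail, with category mixture, truncation/tail length
# distributions (truncated geometric), U-biased tail composition, random
# hairpin-fragment background and optional per-base substitution error.
# Every read is logged in a manifest, so classification can be scored
# read-by-read.

#' Construct a genotype profile for the read generator
#'
#' @param category_probs probabilities of (FL, TR_ONLY, TA_ONLY, TR_TA),
#'   summing to 1; applied to every group unless overridden.
#' @param q_tr,q_ta success parameters of the truncated geometric length
#'   distributions on 1..max (P(k) proportional to (1-q)^(k-1) q): larger q
#'   concentrates mass on short offsets, matching the short-dominated
#'   truncation-tailing matrices seen in vivo.
#' @param max_tr,max_ta maximum truncation/tail lengths drawn (default 8).
#' @param tail_probs per-base tail composition, named A/C/G/U; default 90%
#'   U (uridylation-dominated tailing) with the remainder spread evenly.
#' @param background_fraction fraction of reads drawn as random 15-30 nt
#'   hairpin fragments (default 0.02).
#' @param error_rate per-base substitution probability, in [0, 0.25)
#'   (default 0).
#' @param library_size total reads emitted (default 50000).
#' @param abundance optional named per-group weights (default: equal).
#' @param overrides named list: `group_pattern` (regex on group names) ->
#'   list with optional `category_probs` and/or `weight` multiplier.
#' @param collision_control when TRUE (default), the first tail base is
#'   never the next templated hairpin base, so the generated (tr, ta)
#'   ground truth is unambiguous under either classification dialect. Turn
#'   off for realism runs.
#' @return a `genotype_profile` list.
#' @export
genotype_profile <- function(category_probs = c(FL = 0.94, TR_ONLY = 0.02,
                                                TA_ONLY = 0.02,
                                                TR_TA = 0.02),
                             q_tr = 0.5, q_ta = 0.5,
                             max_tr = 8, max_ta = 8,
                             tail_probs = c(A = 0.1 / 3, C = 0.1 / 3,
                                            G = 0.1 / 3, U = 0.9),
                             background_fraction = 0.02,
                             error_rate = 0,
                             library_size = 50000,
                             abundance = NULL,
                             overrides = list(),
                             collision_control = TRUE) {
  stopifnot(length(category_probs) == 4,
            abs(sum(category_probs) - 1) < 1e-9,
            all(category_probs >= 0),
            length(tail_probs) == 4,
            abs(sum(tail_probs) - 1) < 1e-9,
            q_tr > 0, q_tr <= 1, q_ta > 0, q_ta <= 1,
            background_fraction >= 0, background_fraction < 1,
            error_rate >= 0, error_rate < 0.25,
            library_size > 0)
  names(category_probs) <- c("FL", "TR_ONLY", "TA_ONLY", "TR_TA")
  names(tail_probs) <- c("A", "C", "G", "U")
  structure(list(category_probs = category_probs, q_tr = q_tr, q_ta = q_ta,
                 max_tr = as.integer(max_tr), max_ta = as.integer(max_ta),
                 tail_probs = tail_probs,
                 background_fraction = background_fraction,
                 error_rate = error_rate,
                 library_size = as.integer(library_size),
                 abundance = abundance, overrides = overrides,
                 collision_control = collision_control),
            class = "genotype_profile")
}

#' Preset genotype profiles
#'
#' Named profiles emulating the qualitative isoform structure of the
#' canonical genotypes:
#' \describe{
#'   \item{wildtype_like}{libraries dominated by full-length, methylated
#'     miRNAs (p_FL > 0.9 for every group).}
#'   \item{hen1_like}{loss of 3' methylation: rampant truncation and
#'     U-tailing (high p_TR, p_TRTA).}
#'   \item{hen1_sdn_like}{loss of the SDN exonucleases on top of hen1:
#'     truncation (TR-only + TR+TA) much reduced.}
#'   \item{hen1_heso1_like}{loss of the HESO1 nucleotidyl transferase on
#'     top of hen1: TR+TA mass shifts into TR-only (truncated species no
#'     longer tailed).}
#'   \item{ago10_oe_like}{wild-type background with elevated truncation and
#'     reduced abundance restricted to miR165/166-named groups.}
#' }
#'
#' @param library_size,background_fraction,error_rate passed to every
#'   profile (defaults 50000 / 0.02 / 0).
#' @return named list of `genotype_profile` objects.
#' @export
preset_profiles <- function(library_size = 50000, background_fraction = 0.02,
                            error_rate = 0) {
  mk <- function(p, overrides = list()) {
    genotype_profile(category_probs = p, overrides = overrides,
                     library_size = library_size,
                     background_fraction = background_fraction,
                     error_rate = error_rate)
  }
  list(
    wildtype_like = mk(c(FL = 0.94, TR_ONLY = 0.02, TA_ONLY = 0.02,
                         TR_TA = 0.02)),
    hen1_like = mk(c(FL = 0.35, TR_ONLY = 0.20, TA_ONLY = 0.15,
                     TR_TA = 0.30)),
    hen1_sdn_like = mk(c(FL = 0.60, TR_ONLY = 0.08, TA_ONLY = 0.20,
                         TR_TA = 0.12)),
    hen1_heso1_like = mk(c(FL = 0.35, TR_ONLY = 0.40, TA_ONLY = 0.10,
                           TR_TA = 0.15)),
    ago10_oe_like = mk(c(FL = 0.94, TR_ONLY = 0.02, TA_ONLY = 0.02,
                         TR_TA = 0.02),
                       overrides = list("miR16[56]" = list(
                         category_probs = c(FL = 0.70, TR_ONLY = 0.15,
                                            TA_ONLY = 0.03, TR_TA = 0.12),
                         weight = 0.4)))
  )
}

#' Override a profile for groups matching a pattern
#'
#' @param profile a `genotype_profile`.
#' @param group_pattern regex matched against group names.
#' @param category_probs optional replacement category probabilities.
#' @param weight optional abundance multiplier.
#' @return modified profile.
#' @export
profile_override <- function(profile, group_pattern, category_probs = NULL,
                             weight = NULL) {
  ov <- list()
  if (!is.null(category_probs)) {
    stopifnot(length(category_probs) == 4,
              abs(sum(category_probs) - 1) < 1e-9)
    names(category_probs) <- c("FL", "TR_ONLY", "TA_ONLY", "TR_TA")
    ov$category_probs <- category_probs
  }
  if (!is.null(weight)) ov$weight <- weight
  profile$overrides[[group_pattern]] <- ov
  profile
}

# Truncated geometric pmf on 1..kmax.
tgeom_probs <- function(q, kmax) {
  p <- (1 - q)^(seq_len(kmax) - 1) * q
  p / sum(p)
}

#' Generate a synthetic reference set
#'
#' Random mature sequences (distinct 5' prefixes) embedded in random
#' hairpins with flanking sequence, for driving the generator and the
#' classifier in closed loop. Sequences are synthetic, not genomic.
#'
#' @param n_groups number of miRNA groups (default 8).
#' @param seed RNG seed.
#' @param mature_len mature length (default 21 nt).
#' @param flank hairpin flank length on each side (default 25 nt).
#' @param name_prefix group name stem (default `"synmiR"`).
#' @return a `mirna_refset`.
#' @export
synthetic_refset <- function(n_groups = 8, seed = 1, mature_len = 21,
                             flank = 25, name_prefix = "synmiR") {
  withr::with_seed(derive_seed(seed, "refset"), {
    seqs <- character(0)
    while (length(seqs) < n_groups) {
      s <- paste(sample(RNA_BASES, mature_len, replace = TRUE),
                 collapse = "")
      # distinct 12-mer prefixes keep groups unambiguous at default params
      if (!substr(s, 1, 12) %in% substr(seqs, 1, 12)) {
        seqs <- c(seqs, s)
      }
    }
    names <- sprintf("%s%02d", name_prefix, seq_len(n_groups))
    groups <- tibble::tibble(
      group_name = names,
      members = lapply(names, identity),
      mature = seqs,
      mature_len = as.integer(mature_len),
      hairpin_name = names,
      hairpin = vapply(seqs, function(s) {
        paste0(paste(sample(RNA_BASES, flank, TRUE), collapse = ""), s,
               paste(sample(RNA_BASES, flank, TRUE), collapse = ""))
      }, character(1), USE.NAMES = FALSE),
      mature_offset = as.integer(flank)
    )
    groups$downstream <- substr(groups$hairpin,
                                groups$mature_offset + mature_len + 1,
                                nchar(groups$hairpin))
    structure(list(groups = groups), class = "mirna_refset")
  })
}

#' Generate one synthetic library with its ground-truth manifest
#'
#' Deterministic for a given seed. Per-group read counts are apportioned
#' deterministically from the abundance weights (largest remainder), and
#' each group draws from its own RNG substream derived from (seed, group):
#' two libraries generated with the same seed produce identical reads for
#' every group whose profile parameters agree.
#'
#' @param profile a [genotype_profile()].
#' @param refset reference set the reads are drawn from.
#' @param seed integer seed for this library.
#' @param library_id label used in read ids (default `"lib"`).
#' @return list of class `synthetic_library`: `reads` (tibble `id`, `seq`,
#'   `count` = 1), `manifest` (tibble `id`, `group`, `tr`, `ta`,
#'   `tail_seq`, `category`, `background`, `n_errors`, `error_pos`),
#'   `library_id`, `seed`, `profile`.
#' @export
generate_library <- function(profile, refset, seed = 1, library_id = "lib") {
  stopifnot(inherits(profile, "genotype_profile"),
            inherits(refset, "mirna_refset"))
  g <- refset$groups
  if (profile$max_tr >= min(g$mature_len) - 1) {
    stop("profile max_tr too large for the shortest mature sequence",
         call. = FALSE)
  }

  w <- profile$abundance
  if (is.null(w)) w <- stats::setNames(rep(1, nrow(g)), g$group_name)
  w <- w[g$group_name]
  if (anyNA(w)) stop("abundance weights missing for some groups",
                     call. = FALSE)
  cat_probs <- matrix(rep(profile$category_probs, each = nrow(g)),
                      nrow = nrow(g),
                      dimnames = list(g$group_name,
                                      names(profile$category_probs)))
  for (pat in names(profile$overrides)) {
    ov <- profile$overrides[[pat]]
    hit <- grepl(pat, g$group_name)
    if (!any(hit)) next
    if (!is.null(ov$category_probs)) {
      cat_probs[hit, ] <- matrix(rep(ov$category_probs, each = sum(hit)),
                                 nrow = sum(hit))
    }
    if (!is.null(ov$weight)) w[hit] <- w[hit] * ov$weight
  }

  n_bg <- round(profile$library_size * profile$background_fraction)
  n_mi <- profile$library_size - n_bg
  n_per_group <- apportion(n_mi, as.numeric(w))

  parts <- lapply(seq_len(nrow(g)), function(i) {
    n_g <- n_per_group[i]
    if (n_g == 0) return(NULL)
    withr::with_seed(derive_seed(seed, "group", g$group_name[i]), {
      draw_group_reads(n_g, g[i, ], cat_probs[i, ], profile)
    })
  })
  mi <- dplyr::bind_rows(parts)

  bg <- NULL
  if (n_bg > 0) {
    bg <- withr::with_seed(derive_seed(seed, "background"), {
      draw_background_reads(n_bg, g)
    })
  }

  manifest <- dplyr::bind_rows(mi, bg)
  if (is.null(manifest) || nrow(manifest) == 0) {
    stop("profile produced no reads", call. = FALSE)
  }
  manifest$id <- sprintf("%s_r%07d", library_id, seq_len(nrow(manifest)))

  if (profile$error_rate > 0) {
    manifest <- withr::with_seed(derive_seed(seed, "errors"), {
      apply_errors(manifest, profile$error_rate)
    })
  } else {
    manifest$n_errors <- 0L
    manifest$error_pos <- ""
  }

  reads <- tibble::tibble(id = manifest$id, seq = manifest$seq, count = 1)
  manifest <- manifest[, c("id", "group", "tr", "ta", "tail_seq",
                           "category", "background", "n_errors",
                           "error_pos", "seq")]
  structure(list(reads = reads, manifest = manifest,
                 library_id = library_id, seed = seed, profile = profile),
            class = "synthetic_library")
}

# All reads of one group, inside that group's RNG stream.
draw_group_reads <- function(n_g, ref, cat_p, profile) {
  cats <- sample(names(cat_p), n_g, replace = TRUE, prob = cat_p)
  tr <- integer(n_g)
  ta <- integer(n_g)
  has_tr <- cats %in% c("TR_ONLY", "TR_TA")
  has_ta <- cats %in% c("TA_ONLY", "TR_TA")
  if (any(has_tr)) {
    tr[has_tr] <- sample.int(profile$max_tr, sum(has_tr), replace = TRUE,
                             prob = tgeom_probs(profile$q_tr,
                                                profile$max_tr))
  }
  if (any(has_ta)) {
    ta[has_ta] <- sample.int(profile$max_ta, sum(has_ta), replace = TRUE,
                             prob = tgeom_probs(profile$q_ta,
                                                profile$max_ta))
  }

  tails <- character(n_g)
  idx_ta <- which(ta > 0)
  if (length(idx_ta)) {
    # first tail base: optionally reject the templated continuation base so
    # the (tr, ta) decomposition of the emitted read is unique
    first <- character(length(idx_ta))
    for (t_val in unique(tr[idx_ta])) {
      sel <- idx_ta[tr[idx_ta] == t_val]
      blocked <- next_templated_base(ref, t_val)
      p <- profile$tail_probs
      if (profile$collision_control && !is.na(blocked)) {
        p[blocked] <- 0
        if (sum(p) == 0) {
          stop("collision control left no admissible first tail base",
               call. = FALSE)
        }
        p <- p / sum(p)
      }
      first[match(sel, idx_ta)] <- sample(RNA_BASES, length(sel),
                                          replace = TRUE, prob = p)
    }
    rest_len <- ta[idx_ta] - 1L
    rest <- character(length(idx_ta))
    tot <- sum(rest_len)
    if (tot > 0) {
      pool <- sample(RNA_BASES, tot, replace = TRUE,
                     prob = profile$tail_probs)
      ends <- cumsum(rest_len)
      starts <- ends - rest_len + 1
      joined <- paste(pool, collapse = "")
      rest <- ifelse(rest_len > 0, substring(joined, starts, ends), "")
    }
    tails[idx_ta] <- paste0(first, rest)
  }

  body <- substr(rep(ref$mature, n_g), 1, ref$mature_len - tr)
  tibble::tibble(group = ref$group_name, tr = tr, ta = ta,
                 tail_seq = tails, category = cats, background = FALSE,
                 seq = paste0(body, tails))
}

# The hairpin base a tail would have to avoid to stay recognisably
# non-templated: for a truncated read it is the next mature base; for a
# full-length read it is the first downstream hairpin base (NA at the
# hairpin boundary).
next_templated_base <- function(ref, tr) {
  if (tr > 0) {
    substr(ref$mature, ref$mature_len - tr + 1, ref$mature_len - tr + 1)
  } else if (nchar(ref$downstream) > 0) {
    substr(ref$downstream, 1, 1)
  } else {
    NA_character_
  }
}

draw_background_reads <- function(n_bg, groups) {
  hp_i <- sample.int(nrow(groups), n_bg, replace = TRUE)
  len <- sample(15:30, n_bg, replace = TRUE)
  hp_len <- nchar(groups$hairpin[hp_i])
  len <- pmin(len, hp_len)
  start <- floor(stats::runif(n_bg) * (hp_len - len + 1)) + 1
  tibble::tibble(group = NA_character_, tr = NA_integer_, ta = NA_integer_,
                 tail_seq = NA_character_, category = "background",
                 background = TRUE,
                 seq = substr(groups$hairpin[hp_i], start, start + len - 1))
}

apply_errors <- function(manifest, error_rate) {
  seqs <- strsplit(manifest$seq, "", fixed = TRUE)
  n_err <- integer(nrow(manifest))
  pos_str <- character(nrow(manifest))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    hit <- which(stats::runif(length(s)) < error_rate)
    if (length(hit)) {
      for (j in hit) {
        s[j] <- sample(setdiff(RNA_BASES, s[j]), 1)
      }
      seqs[[i]] <- s
    }
    n_err[i] <- length(hit)
    pos_str[i] <- paste(hit, collapse = ",")
  }
  manifest$seq <- vapply(seqs, paste, character(1), collapse = "")
  manifest$n_errors <- n_err
  manifest$error_pos <- pos_str
  manifest
}

#' Score classification against a ground-truth manifest
#'
#' Joins per-read calls onto the manifest by read id and reports (i) the
#' confusion table of true versus called category, (ii) the maximum
#' absolute difference between true and called per-group category
#' proportions, and (iii) the fraction of background reads that were
#' (mis)assigned to a miRNA group.
#'
#' @param manifest `manifest` element of a [generate_library()] result (or
#'   the whole object).
#' @param by_read per-read classification: `reads` element of an
#'   `isotrim_library` or a [classify_reads()] result.
#' @return list with `confusion` (table), `max_composition_error`,
#'   `background_assigned_fraction` (NA with no background reads) and
#'   `n_reads`.
#' @export
recovery_report <- function(manifest, by_read) {
  if (inherits(manifest, "synthetic_library")) manifest <- manifest$manifest
  if (inherits(by_read, "isotrim_library")) by_read <- by_read$reads
  called <- by_read |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      called_status = .data$status[1],
      called_group = .data$group[1],
      called_category = .data$category[1],
      .groups = "drop"
    )
  j <- dplyr::left_join(manifest, called, by = "id")
  j$called_label <- ifelse(j$called_status == "assigned",
                           j$called_category, j$called_status)
  confusion <- table(true = j$category, called = j$called_label)

  mi <- j[!j$background, ]
  true_p <- mi |>
    dplyr::count(.data$group, .data$category, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  call_p <- mi[mi$called_status == "assigned", ] |>
    dplyr::count(.data$called_group, .data$called_category, name = "n") |>
    dplyr::group_by(.data$called_group) |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::rename(group = "called_group", category = "called_category")
  cmp <- dplyr::full_join(true_p[, c("group", "category", "p")],
                          call_p[, c("group", "category", "p")],
                          by = c("group", "category"),
                          suffix = c("_true", "_called"))
  cmp$p_true[is.na(cmp$p_true)] <- 0
  cmp$p_called[is.na(cmp$p_called)] <- 0
  max_err <- if (nrow(cmp)) max(abs(cmp$p_true - cmp$p_called)) else NA_real_

  bg <- j[j$background, ]
  bg_frac <- if (nrow(bg)) mean(bg$called_status == "assigned") else NA_real_

  list(confusion = confusion, max_composition_error = max_err,
       background_assigned_fraction = bg_frac, n_reads = nrow(j))
}
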