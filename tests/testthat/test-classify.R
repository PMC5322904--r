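test_that("3' decomposition yields the four categories on worked examples", {
  rs <- mini_refset()
  cases <- list(
    list(seq = T21, tr = 0L, tail = "", cat = "FL"),
    list(seq = paste0(substr(T21, 1, 19), "UU"), tr = 2L, tail = "UU",
         cat = "TR_TA"),
    list(seq = paste0(T21, "U"), tr = 0L, tail = "U", cat = "TA_ONLY"),
    list(seq = substr(T21, 1, 18), tr = 3L, tail = "", cat = "TR_ONLY")
  )
  for (cs in cases) {
    call <- classify_read(cs$seq, rs)
    expect_equal(call$status, "assigned")
    expect_equal(call$group, "miR900a")
    expect_equal(call$tr, cs$tr)
    expect_equal(call$tail_seq, cs$tail)
    expect_equal(call$category, cs$cat)
    # reconstruction invariant
    expect_equal(paste0(substr(T21, 1, 21 - call$tr), call$tail_seq), cs$seq)
  }
})

test_that("reads matching fewer than min_match bases stay unassigned", {
  rs <- mini_refset()
  # 10 matched bases < default min_match 12; also shorter than the length
  # filter, so pad the comparison with an 16-nt read diverging at base 11
  short <- classify_read(substr(T21, 1, 10), rs)
  expect_true(short$status %in% c("unassigned", "filtered"))
  div <- paste0(substr(T21, 1, 10), "GGGGGG") # diverges at position 11
  expect_equal(classify_read(div, rs)$status, "unassigned")
  ok <- classify_read(substr(T21, 1, 15), rs)
  expect_equal(ok$status, "assigned")
  expect_equal(ok$tr, 6L)
})

test_that("classification equals the exhaustive decomposition oracle", {
  rs <- mini_refset()
  params <- classify_params()
  withr::local_seed(421)
  bases <- c("A", "C", "G", "U")
  for (i in 1:1000) {
    mode <- sample(c("derived", "random"), 1)
    if (mode == "derived") {
      m <- rs$groups$mature[sample(2, 1)]
      tr <- sample(0:10, 1)
      ta <- sample(0:10, 1)
      s <- paste0(substr(m, 1, 21 - tr),
                  paste(sample(bases, ta, replace = TRUE), collapse = ""))
    } else {
      s <- paste(sample(bases, sample(15:30, 1), replace = TRUE),
                 collapse = "")
    }
    got <- classify_read(s, rs, params)
    want <- oracle_classify(s, rs, params)
    expect_equal(got$status[1], want$status, info = s)
    if (want$status == "assigned") {
      expect_equal(got$group, want$group, info = s)
      expect_equal(got$tr, as.integer(want$tr), info = s)
      expect_equal(got$tail_seq, want$tail, info = s)
    }
  }
})

test_that("counts are conserved and aggregation is order-invariant", {
  rs <- mini_refset()
  withr::local_seed(99)
  bases <- c("A", "C", "G", "U")
  seqs <- c(
    replicate(60, {
      m <- rs$groups$mature[sample(2, 1)]
      paste0(substr(m, 1, 21 - sample(0:6, 1)),
             paste(sample(bases, sample(0:4, 1), replace = TRUE),
                   collapse = ""))
    }),
    replicate(20, paste(sample(bases, sample(10:34, 1), replace = TRUE),
                        collapse = ""))
  )
  reads <- tibble::tibble(seq = seqs, count = sample(1:5, 80, replace = TRUE))
  lib <- classify_library(reads, rs)
  s <- lib$stats
  expect_equal(s$assigned + s$unassigned + s$ambiguous_dropped,
               s$total_count)
  expect_equal(s$total_count, sum(reads$count))
  expect_equal(sum(lib$calls$count), s$assigned)

  perm <- sample(nrow(reads))
  lib2 <- classify_library(reads[perm, ], rs)
  expect_equal(lib$calls, lib2$calls)
  expect_equal(lib$stats, lib2$stats)
})

test_that("raising max_tr or max_ta never decreases the assigned count", {
  rs <- mini_refset()
  withr::local_seed(7)
  bases <- c("A", "C", "G", "U")
  reads <- tibble::tibble(seq = replicate(150, {
    m <- rs$groups$mature[sample(2, 1)]
    paste0(substr(m, 1, 21 - sample(0:8, 1)),
           paste(sample(bases, sample(0:8, 1), replace = TRUE),
                 collapse = ""))
  }))
  assigned_at <- function(tr, ta) {
    classify_library(reads, rs,
                     classify_params(max_tr = tr, max_ta = ta))$stats$assigned
  }
  base <- assigned_at(3, 3)
  expect_gte(assigned_at(5, 3), base)
  expect_gte(assigned_at(3, 5), base)
  expect_gte(assigned_at(8, 8), assigned_at(5, 5))
})

test_that("equal-truncation ties are dropped or split fractionally", {
  # two matures differing only at their last base tie for any read
  # truncated past position 20
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "m.fa"); hp <- file.path(dir, "h.fa")
  m1 <- paste0(substr(T21, 1, 20), "A")
  m2 <- paste0(substr(T21, 1, 20), "G")
  writeLines(c(">miR910a", m1, ">miR911a", m2), mat)
  writeLines(c(">miR910a", paste0("GG", m1, "CC"),
               ">miR911a", paste0("AA", m2, "UU")), hp)
  rs <- load_references(mat, hp)

  tie_read <- tibble::tibble(seq = substr(T21, 1, 20), count = 4)
  dropped <- classify_library(tie_read, rs)
  expect_equal(dropped$stats$ambiguous_dropped, 4)
  expect_equal(nrow(dropped$calls), 0)

  frac <- classify_library(tie_read, rs,
                           classify_params(ambiguous_policy = "fractional"))
  expect_equal(nrow(frac$calls), 2)
  expect_equal(frac$calls$count, c(2, 2))
  expect_equal(frac$stats$assigned, 4)
  expect_setequal(frac$calls$group, c("miR910a", "miR911a"))

  # an unambiguous full-length read still assigns uniquely
  expect_equal(classify_read(m1, rs)$group, "miR910a")
})

test_that("template_extended dialect records templated extension length", {
  rs <- mini_refset() # downstream of miR900a begins "GGAUCC..."
  read <- paste0(T21, "GGU")
  anchored <- classify_read(read, rs)
  expect_equal(anchored$category, "TA_ONLY")
  expect_equal(anchored$tail_seq, "GGU")
  expect_equal(anchored$templated_ext, 0L)

  ext <- classify_read(read, rs,
                       classify_params(tail_dialect = "template_extended"))
  expect_equal(ext$tr, 0L)
  expect_equal(ext$tail_seq, "GGU")
  expect_equal(ext$templated_ext, 2L)
})

test_that("empty input yields empty calls and zeroed stats", {
  rs <- mini_refset()
  lib <- classify_library(tibble::tibble(seq = character()), rs)
  expect_equal(nrow(lib$calls), 0)
  expect_equal(lib$stats$total_count, 0)
  expect_equal(lib$stats$assigned, 0)
})
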