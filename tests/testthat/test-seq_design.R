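test_that("ARE scanner handles the canonical registration and length cases", {
  m <- scan_ares("AUUUA")
  expect_equal(nrow(m), 1L)
  expect_equal(m$length, 5L)
  expect_equal(m$start_registration, 0L)
  expect_equal(m$effective_length, 5L)

  # UUAUUU is an ARE despite containing no AUUUA
  m <- scan_ares("UUAUUU")
  expect_equal(m$length, 6L)
  expect_equal(m$start_registration, 2L)
  expect_equal(m$effective_length, 8L)

  # UAUUU is too short at its registration
  expect_equal(nrow(scan_ares("UAUUU")), 0L)

  m <- scan_ares("GAUUUAUUUAG")
  expect_equal(m$start, 1L)
  expect_equal(m$length, 9L)
  expect_equal(m$start_registration, 0L)
  expect_equal(m$effective_length, 9L)
  expect_equal(m$naive_pentamer_count, 1L)

  m <- scan_ares("UUUAUUU")
  expect_equal(m$length, 7L)
  expect_equal(m$start_registration, 1L)
  expect_equal(m$end_registration, 0L)

  # T and lowercase are normalized; invalid characters name their position
  expect_equal(scan_ares("atttta")$length, scan_ares("AUUUUA")$length)
  expect_error(scan_ares("AUUNA"), "position 4")
})

test_that("ARE scanner agrees with the brute-force oracle", {
  for (s in all_au_strings(10)) expect_same_matches(s)
  for (s in random_rna(200, 30, seed = 101)) expect_same_matches(s)
  # AU-biased sequences hit many overlapping runs
  for (s in random_rna(100, 50, seed = 102,
                       alphabet = c("A", "U", "A", "U", "G", "C"))) {
    expect_same_matches(s)
  }
})

test_that("match fields satisfy the registration arithmetic invariants", {
  seqs <- random_rna(300, 60, seed = 103,
                     alphabet = c("A", "U", "U", "A", "G", "C"))
  m <- scan_ares(seqs)
  expect_gt(nrow(m), 50)
  expect_equal(m$effective_length - m$length, m$start_registration)
  expect_equal((m$start_registration + m$length) %% 4L, m$end_registration)
  expect_equal(m$naive_pentamer_count,
               (m$length + m$start_registration - 2L) %/% 4L)
  # matched substrings equal the periodic pattern at their registration
  for (i in seq_len(nrow(m))) {
    expect_equal(m$match[i],
                 oracle_pattern(m$start_registration[i], m$length[i]))
  }
  # phase-0, length 4n+1 runs: naive pentamer count = tiling pentamers - 1
  g0 <- m[m$start_registration == 0L & (m$length - 1L) %% 4L == 0L, ]
  expect_equal(g0$naive_pentamer_count, (g0$length - 1L) %/% 4L - 1L)
})

test_that("total effective length sums the per-match formula", {
  expect_equal(total_effective_length("AUUUAGGUUAUUU"), 5L + 8L)
  expect_equal(total_effective_length("GGCC"), 0L)
  seqs <- random_rna(50, 80, seed = 104, alphabet = c("A", "U", "U", "G"))
  recompute <- vapply(seqs, function(s) {
    m <- scan_ares(s)
    as.integer(sum(m$effective_length))
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(total_effective_length(seqs), recompute)
})

test_that("cluster assignment picks the largest matching motif", {
  expect_equal(as.character(assign_cluster("GCAUUUAUUUAUUUACG")), "C3")
  expect_equal(as.character(assign_cluster("UAUAAUUUAAUAU")), "C1")
  expect_equal(as.character(assign_cluster("GGAUUUAGG")), "AUUUA_only")
  expect_equal(as.character(assign_cluster("GGCGCGCC")), "none")
  expect_equal(as.character(assign_cluster("UUAUUUAUUUAAU")), "C2")
  expect_equal(as.character(assign_cluster(strrep("AUUU", 5))), "C4")
  expect_equal(
    as.character(assign_cluster(paste0(strrep("AUUU", 5), "AUUUA"))), "C5"
  )
  expect_true(is.ordered(assign_cluster("AUUUA")))
})

test_that("cluster labels never drop when one more AUUUA repeat is appended", {
  flanks <- random_rna(30, 10, seed = 105, alphabet = c("G", "C", "A"))
  for (n_rep in c(3L, 4L)) {
    motif <- paste0("AUUU", strrep("AUUU", n_rep - 1L), "A")
    base <- paste0(flanks, motif, rev(flanks))
    extended <- paste0(flanks, motif, "UUUA", rev(flanks))
    expect_true(all(assign_cluster(extended) >= assign_cluster(base)))
  }
})

test_that("CDE scanner reports maximal strict Watson-Crick stems", {
  m <- scan_cdes("CCUUCCACGAAGG")
  expect_equal(m$stem_length, 2L)
  expect_equal(m$core_sequence, "UUCCACGAA")

  expect_equal(scan_cdes("UUCCGUGAA")$stem_length, 0L)

  m <- scan_cdes("AGACUGUUCCGUGAACAGUCA")
  expect_equal(m$stem_length, 5L)
  expect_equal(m$upstream_stem, "GACUG")
  # downstream stem is the reverse complement of the upstream stem
  expect_equal(m$downstream_stem, revcomp_rna(m$upstream_stem))

  expect_equal(nrow(scan_cdes("UUGCACGAA")), 0L)

  # cap at 5 even when more complementary pairs exist
  up <- "GACUGA"
  m <- scan_cdes(paste0(up, "UUCCGUGAA", revcomp_rna(up)))
  expect_equal(m$stem_length, 5L)

  # all four Y/R instantiations of the core are recognized
  for (y1 in c("C", "U")) for (r in c("A", "G")) for (y2 in c("C", "U")) {
    core <- paste0("UUC", y1, r, y2, "GAA")
    expect_equal(nrow(scan_cdes(core)), 1L)
  }
})

test_that("stems found in random sequences verify by reverse-complement", {
  seqs <- random_rna(400, 40, seed = 106)
  seqs <- paste0(substr(seqs, 1, 20), "UUCCGUGAA", substr(seqs, 21, 40))
  m <- scan_cdes(seqs)
  expect_gt(nrow(m), 300)
  nz <- m[m$stem_length > 0L, ]
  expect_equal(nz$downstream_stem, revcomp_rna(nz$upstream_stem))
  expect_true(all(m$stem_length <= 5L))
})

test_that("UTR windowing tiles, pads, and drops short tails", {
  w <- segment_utr(strrep("ACGU", 100)) # 400 nt
  expect_equal(w$start, c(0L, 80L, 160L, 240L, 320L))
  expect_equal(w$pad_length, c(0L, 0L, 0L, 0L, 80L))
  expect_equal(nchar(w$sequence), rep(160L, 5))
  expect_equal(substr(w$sequence[5], 81, 160), substr(neutral_pad(), 1, 80))

  expect_equal(nrow(segment_utr(strrep("A", 19))), 0L)
  expect_error(segment_utr(""), "empty")
  expect_error(segment_utr(strrep("A", 100), pad_sequence = "ACGU"),
               "pad_sequence")

  # gc_fraction is computed on the padded sequence
  expect_equal(w$gc_fraction, gc_fraction(w$sequence))
})

test_that("ARE mutation alternates C/G down the central U positions", {
  expect_equal(mutate_are("AUUUAUUUA"), "AUCUAUGUA")
  expect_equal(mutate_are("AUUUA"), "AUCUA")
  expect_equal(mutate_are("AUUUAUUUAUUUA"), "AUCUAUGUAUCUA")
  # non-phase-0 run with no complete pentamer: the UUU triple centre mutates
  expect_equal(mutate_are("UUAUUU"), "UUAUCU")
  # flanks untouched
  expect_equal(mutate_are("GGAUUUAGG"), "GGAUCUAGG")
  expect_error(
    mutate_are("AUUUA", list(start = 0L, length = 9L, start_registration = 0L)),
    "inconsistent"
  )
})

test_that("mutated runs contain no residual ARE spanning the original run", {
  withr::with_seed(107, {
    for (i in 1:100) {
      L <- sample(5:21, 1)
      g <- if (L == 5) 0L else sample(0:3, 1)
      left <- paste(sample(c("G", "C"), 6, TRUE), collapse = "")
      right <- paste(sample(c("G", "C"), 6, TRUE), collapse = "")
      s <- paste0(left, oracle_pattern(g, L), right)
      mut <- mutate_are(s)
      m <- scan_ares(mut)
      overlap <- m[m$start < 6 + L & m$start + m$length > 6, ]
      expect_equal(nrow(overlap), 0L)
    }
  })
})

test_that("CDE mutation disrupts the core or permutes the span", {
  expect_equal(mutate_cde("UUCCGUGAA", mode = "core"), "UAGCGUGAA")
  s <- "AGACUGUUCCGUGAACAGUCA"
  m <- scan_cdes(s)
  sh <- mutate_cde(s, m, mode = "shuffle", seed = 42)
  expect_equal(nchar(sh), nchar(s))
  # the shuffled span keeps its nucleotide multiset; guards untouched
  span <- function(x) substr(x, 2, 20)
  expect_equal(sort(strsplit(span(sh), "")[[1]]),
               sort(strsplit(span(s), "")[[1]]))
  expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  expect_equal(substr(sh, 21, 21), substr(s, 21, 21))
  # same seed, same permutation
  expect_identical(sh, mutate_cde(s, m, mode = "shuffle", seed = 42))
  expect_error(mutate_cde(s, m, mode = "shuffle"), "seed")
  expect_error(mutate_cde("GGGGGGGGG", mode = "core"), "no CDE")
})
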