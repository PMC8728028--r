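#' Segment a 3' UTR into fixed-width assay windows
#'
#' Tiles a 3' UTR with sliding windows (default 160 nt, shifted by 80 nt),
#' the fragment size used in reporter-assay library design. Windows start at
#' 0, `shift`, `2 * shift`, ...; a terminal window shorter than `window` but
#' at least `min_len` nt is right-padded to full window length from
#' `pad_sequence` (a neutral sequence with minimal regulatory activity), and
#' shorter tails are dropped.
#'
#' @param utr_sequence A single nucleotide string (T accepted, mapped to U).
#' @param window Window width in nt.
#' @param shift Offset between successive window starts, in nt.
#' @param min_len Minimum unpadded window length to keep, in nt.
#' @param pad_sequence Sequence used to right-pad terminal windows; must be at
#'   least `window` nt. Defaults to a bundled synthetic neutral sequence
#'   (AU/GC balanced, free of ARE and CDE motifs).
#' @param transcript_id,chromosome Labels carried into the output.
#' @return A tibble with one row per window: `segment_id`, `transcript_id`,
#'   `chromosome`, `start`, `end` (0-based half-open UTR coordinates),
#'   `sequence`, `pad_length`, `role` (`"reference"`), `partner_id`,
#'   `gc_fraction`.
#' @examples
#' segment_utr(strrep("ACGU", 100))
#' @export
segment_utr <- function(utr_sequence, window = 160L, shift = 80L,
                        min_len = 20L, pad_sequence = neutral_pad(),
                        transcript_id = "utr", chromosome = NA_character_) {
  stopifnot(length(utr_sequence) == 1L, window >= 1L, shift >= 1L)
  utr_sequence <- normalize_rna(utr_sequence)
  n <- nchar(utr_sequence)
  if (n == 0L) stop("empty UTR sequence", call. = FALSE)
  pad_sequence <- normalize_rna(pad_sequence)
  if (nchar(pad_sequence) < window) {
    stop("pad_sequence must be at least `window` nt long", call. = FALSE)
  }
  starts <- seq.int(0L, n - 1L, by = shift)
  len <- pmin(window, n - starts)
  keep <- len >= min_len
  starts <- starts[keep]
  len <- len[keep]
  if (length(starts) == 0L) {
    return(tibble::tibble(
      segment_id = character(), transcript_id = character(),
      chromosome = character(), start = integer(), end = integer(),
      sequence = character(), pad_length = integer(), role = character(),
      partner_id = character(), gc_fraction = double()
    ))
  }
  raw <- substr(rep(utr_sequence, length(starts)), starts + 1L, starts + len)
  pad_len <- window - len
  seqs <- ifelse(
    pad_len > 0L,
    paste0(raw, substr(rep(pad_sequence, length(starts)), 1L, pad_len)),
    raw
  )
  tibble::tibble(
    segment_id = sprintf("%s_w%d", transcript_id, starts),
    transcript_id = transcript_id,
    chromosome = chromosome,
    start = as.integer(starts),
    end = as.integer(starts + len),
    sequence = seqs,
    pad_length = as.integer(pad_len),
    role = "reference",
    partner_id = NA_character_,
    gc_fraction = gc_fraction(seqs)
  )
}

#' Bundled neutral padding sequence
#'
#' A synthetic 160-nt sequence with balanced composition and no ARE
#' (periodic AUUUA run of length >= 5) or CDE (UUCYRYGAA core) motif,
#' used to right-pad terminal UTR windows. It stands in for an
#' assay-specific padding fragment, which users may supply instead via the
#' `pad_sequence` argument of [segment_utr()].
#'
#' @return A single 160-nt RNA string.
#' @export
neutral_pad <- function() NEUTRAL_PAD

#' Scan a sequence for AU-rich elements (AREs)
#'
#' Finds all maximal perfect matches to the repeating AUUUA pattern
#' `AUUUAUUUAUUUA...` of length at least 6 at any registration, plus maximal
#' length-5 matches that equal the exact `AUUUA` pentamer. The *starting
#' registration* g is the phase of the first matched nucleotide within the
#' pentamer period (AUUU* = 0, UUUA* = 1, UUAU* = 2, UAUU* = 3); sequences
#' such as `UUAUUU` are therefore AREs even though they contain no `AUUUA`.
#' The *effective length* is `length + g`, the length the ARE would have if
#' extended leftward to phase 0.
#'
#' @param x Character vector of sequences (T accepted), optionally named;
#'   names become `seq_id`.
#' @return A tibble with one row per match: `seq_id`, `start` (0-based),
#'   `length`, `start_registration`, `end_registration`, `effective_length`,
#'   `naive_pentamer_count` (`floor((length + g - 2) / 4)`), `match`.
#'   Matches are sorted by `start` within each sequence and are non-nested.
#' @examples
#' scan_ares(c("GAUUUAUUUAG", "UUAUUU"))
#' @export
scan_ares <- function(x) {
  x <- normalize_rna(x)
  ids <- names(x) %||% as.character(seq_along(x))
  res <- purrr::map2(x, ids, scan_ares_one)
  dplyr::bind_rows(res)
}

# Core scanner: 0-based starts, lengths, and registrations of all maximal
# valid runs, sorted by start. Plain vectors for speed; the tibble interface
# sits on top.
are_runs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  a_out <- integer(0); l_out <- integer(0); g_out <- integer(0)
  if (n >= 5L) {
    pos <- seq_len(n) - 1L # 0-based
    for (c_off in 0:3) {
      phase <- (pos + c_off) %% 4L
      ok <- ch == ifelse(phase == 0L, "A", "U")
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts0 <- ends - r$lengths # 0-based starts
      j <- which(r$values)
      L <- r$lengths[j]
      a <- starts0[j]
      g <- (a + c_off) %% 4L
      keep <- L >= 6L | (L == 5L & g == 0L)
      a_out <- c(a_out, a[keep])
      l_out <- c(l_out, L[keep])
      g_out <- c(g_out, g[keep])
    }
  }
  o <- order(a_out)
  list(start = as.integer(a_out[o]), length = as.integer(l_out[o]),
       registration = as.integer(g_out[o]))
}

scan_ares_one <- function(s, id) {
  runs <- are_runs(s)
  a <- runs$start; L <- runs$length; g <- runs$registration
  tibble::tibble(
    seq_id = rep(id, length(a)),
    start = a,
    length = L,
    start_registration = g,
    end_registration = (g + L) %% 4L,
    effective_length = L + g,
    naive_pentamer_count = (L + g - 2L) %/% 4L,
    match = substr(rep(s, length(a)), a + 1L, a + L)
  )
}

#' Total effective length of all AREs in a sequence
#'
#' The sum of `effective_length` (length + starting registration) over all
#' maximal AREs found by [scan_ares()]; a summary statistic for long UTRs
#' carrying several AREs.
#'
#' @param x Character vector of sequences.
#' @return Integer vector, 0 where no ARE is present.
#' @export
total_effective_length <- function(x) {
  x <- normalize_rna(x)
  vapply(x, function(s) {
    runs <- are_runs(s)
    as.integer(sum(runs$length + runs$registration))
  }, integer(1), USE.NAMES = FALSE)
}

#' Longest ARE per sequence
#'
#' Picks the representative ARE of each sequence: the longest match, with
#' ties broken by the leftmost start.
#'
#' @param x Character vector of sequences, optionally named.
#' @return A tibble with one row per sequence (`seq_id`, ARE fields as in
#'   [scan_ares()]); all-NA fields where no ARE is present.
#' @export
longest_are <- function(x) {
  x <- normalize_rna(x)
  ids <- names(x) %||% as.character(seq_along(x))
  pick <- purrr::map2(x, ids, function(s, id) {
    runs <- are_runs(s)
    if (length(runs$start) == 0L) {
      return(list(id = id, a = NA_integer_, L = NA_integer_, g = NA_integer_,
                  match = NA_character_))
    }
    i <- order(-runs$length, runs$start)[1L]
    list(id = id, a = runs$start[i], L = runs$length[i],
         g = runs$registration[i],
         match = substr(s, runs$start[i] + 1L, runs$start[i] + runs$length[i]))
  })
  pick <- unname(pick)
  a <- purrr::map_int(pick, "a"); L <- purrr::map_int(pick, "L")
  g <- purrr::map_int(pick, "g")
  tibble::tibble(
    seq_id = purrr::map_chr(pick, "id"),
    start = a,
    length = L,
    start_registration = g,
    end_registration = (g + L) %% 4L,
    effective_length = L + g,
    naive_pentamer_count = (L + g - 2L) %/% 4L,
    match = purrr::map_chr(pick, "match")
  )
}

# Cluster motif regexes, checked from largest to smallest. Clusters 3-5 are
# 3/4/5 exact overlapping AUUUA repeats (13/17/21 nt); clusters 1 and 2 are
# 13-nt motifs with AU-rich flanks around one or two AUUUA cores.
CLUSTER_PATTERNS <- c(
  C5 = "AUUUAUUUAUUUAUUUAUUUA",
  C4 = "AUUUAUUUAUUUAUUUA",
  C3 = "AUUUAUUUAUUUA",
  C2 = "[AU][AU]AUUUAUUUA[AU][AU]",
  C1 = "[AU][AU][AU][AU]AUUUA[AU][AU][AU][AU]"
)

CLUSTER_LEVELS <- c("none", "AUUUA_only", "C1", "C2", "C3", "C4", "C5")

#' Assign the ARED-Plus-style cluster label of a sequence
#'
#' Classifies a sequence by the largest ARE cluster motif it contains:
#' clusters 3-5 are 3, 4, or 5 exact overlapping AUUUA repeats; clusters 1
#' and 2 are 13-nt motifs of one or two AUUUA cores flanked by AU-rich (W =
#' A/U) sequence. Sequences containing the minimal `AUUUA` pentamer but no
#' cluster motif are labelled `AUUUA_only`; all others `none`. The highest
#' matching cluster wins.
#'
#' @param x Character vector of sequences.
#' @return An ordered factor with levels
#'   `none < AUUUA_only < C1 < C2 < C3 < C4 < C5`.
#' @examples
#' assign_cluster(c("GGAUUUAGG", "UAUAAUUUAAUAU", "GGCGCGCC"))
#' @export
assign_cluster <- function(x) {
  x <- normalize_rna(x)
  lab <- rep("none", length(x))
  lab[stringr::str_detect(x, stringr::fixed("AUUUA"))] <- "AUUUA_only"
  for (cl in rev(names(CLUSTER_PATTERNS))) { # C1 up to C5: later wins
    lab[stringr::str_detect(x, CLUSTER_PATTERNS[[cl]])] <- cl
  }
  factor(lab, levels = CLUSTER_LEVELS, ordered = TRUE)
}

#' Scan a sequence for constitutive decay elements (CDEs)
#'
#' Finds every occurrence of the degenerate CDE core `UUCYRYGAA`
#' (Y = C/U, R = A/G) and reports the maximal lower-stem length: the largest
#' n <= 5 such that the n nt immediately upstream of the core and the n nt
#' immediately downstream are strict Watson-Crick reverse complements
#' (A-U, G-C; no wobble).
#'
#' @param x Character vector of sequences, optionally named.
#' @return A tibble with one row per core occurrence: `seq_id`, `core_start`
#'   (0-based), `core_sequence`, `stem_length`, `upstream_stem`,
#'   `downstream_stem`.
#' @examples
#' scan_cdes("CCUUCCACGAAGG")
#' @export
scan_cdes <- function(x) {
  x <- normalize_rna(x)
  ids <- names(x) %||% as.character(seq_along(x))
  purrr::map2_dfr(x, ids, scan_cdes_one)
}

CDE_CORE_REGEX <- "(?=UUC[CU][AG][CU]GAA)"

scan_cdes_one <- function(s, id) {
  hits <- gregexpr(CDE_CORE_REGEX, s, perl = TRUE)[[1]]
  empty <- tibble::tibble(
    seq_id = character(), core_start = integer(), core_sequence = character(),
    stem_length = integer(), upstream_stem = character(),
    downstream_stem = character()
  )
  if (hits[1L] == -1L) return(empty)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  purrr::map_dfr(as.integer(hits), function(p) { # p: 1-based core start
    stem <- 0L
    while (stem < 5L) {
      i <- p - stem - 1L       # next upstream position (1-based)
      j <- p + 9L + stem       # next downstream position (1-based)
      if (i < 1L || j > n) break
      if (comp[[ch[i]]] != ch[j]) break
      stem <- stem + 1L
    }
    tibble::tibble(
      seq_id = id,
      core_start = p - 1L,
      core_sequence = substr(s, p, p + 8L),
      stem_length = stem,
      upstream_stem = if (stem > 0L) substr(s, p - stem, p - 1L) else "",
      downstream_stem = if (stem > 0L) substr(s, p + 9L, p + 8L + stem) else ""
    )
  })
}

#' Mutate an ARE by disrupting its AUUUA pentamers
#'
#' Reproduces the designed ARE mutations: AUUUA pentamers tile the matched
#' run starting from its first phase-0 (pattern `A`) position at 4-nt steps,
#' and the central U of each tiled pentamer whose centre lies inside the run
#' is replaced by C or G, alternating along the sequence (e.g.
#' `AUUUAUUUA` becomes `AUCUAUGUA`). For runs whose registration leaves no
#' complete pentamer (e.g. `UUAUUU`), the centre of the phase-aligned UUU
#' triple is mutated.
#'
#' @param sequence A single nucleotide string.
#' @param match A one-row data frame (or list) with `start`, `length`, and
#'   `start_registration` as produced by [scan_ares()]. If `NULL`, every ARE
#'   found in `sequence` is mutated.
#' @return The mutated sequence (uppercase).
#' @examples
#' mutate_are("AUUUAUUUA")
#' @export
mutate_are <- function(sequence, match = NULL) {
  stopifnot(length(sequence) == 1L)
  sequence <- normalize_rna(sequence)
  if (is.null(match)) {
    matches <- scan_ares_one(sequence, "s")
    if (nrow(matches) == 0L) return(sequence)
  } else {
    matches <- tibble::as_tibble(match[c("start", "length", "start_registration")])
  }
  ch <- strsplit(sequence, "")[[1]]
  for (r in seq_len(nrow(matches))) {
    a <- as.integer(matches$start[r])
    L <- as.integer(matches$length[r])
    g <- as.integer(matches$start_registration[r])
    run <- substr(sequence, a + 1L, a + L)
    if (is.na(a) || is.na(L) || is.na(g) || a < 0L || a + L > length(ch) ||
        run != periodic_pattern(g, L)) {
      stop("ARE match is inconsistent with the sequence", call. = FALSE)
    }
    o <- (4L - g) %% 4L # first phase-0 offset within the run
    centers <- seq.int(o + 2L, by = 4L, length.out = max(0L, (L - o - 3L) %/% 4L + 1L))
    centers <- centers[centers < L]
    if (length(centers) > 0L) {
      sub <- rep_len(c("C", "G"), length(centers))
      ch[a + centers + 1L] <- sub
    }
  }
  paste(ch, collapse = "")
}

#' Mutate a CDE core or shuffle the CDE span
#'
#' Two designed CDE disruptions: `mode = "core"` mutates the first two
#' positions of the 9-nt core (`UUCYRYGAA` to `UAGYRYGAA`, i.e. U to A and
#' C to G at core positions 1 and 2, 0-based); `mode = "shuffle"` replaces
#' the stem + core + stem span with a seeded random permutation of itself
#' (identical length and nucleotide composition).
#'
#' @param sequence A single nucleotide string.
#' @param match A one-row data frame (or list) with `core_start` and
#'   `stem_length` as produced by [scan_cdes()]. If `NULL`, the first CDE
#'   found is used.
#' @param mode `"core"` or `"shuffle"`.
#' @param seed Integer seed for the shuffle permutation (required for
#'   `mode = "shuffle"`).
#' @return The mutated sequence.
#' @examples
#' mutate_cde("UUCCGUGAA", mode = "core")
#' @export
mutate_cde <- function(sequence, match = NULL, mode = c("core", "shuffle"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(sequence) == 1L)
  sequence <- normalize_rna(sequence)
  if (is.null(match)) {
    found <- scan_cdes_one(sequence, "s")
    if (nrow(found) == 0L) stop("no CDE core found in sequence", call. = FALSE)
    match <- found[1L, ]
  }
  p <- as.integer(match$core_start) # 0-based
  stem <- as.integer(match$stem_length)
  core <- substr(sequence, p + 1L, p + 9L)
  if (is.na(p) || p < 0L || p + 9L > nchar(sequence) ||
      !grepl("^UUC[CU][AG][CU]GAA$", core)) {
    stop("CDE match is inconsistent with the sequence", call. = FALSE)
  }
  ch <- strsplit(sequence, "")[[1]]
  if (mode == "core") {
    ch[p + 2L] <- "A" # core position 1 (0-based): U -> A
    ch[p + 3L] <- "G" # core position 2 (0-based): C -> G
  } else {
    if (is.null(seed)) stop("shuffle mode requires a seed", call. = FALSE)
    span <- seq.int(p - stem + 1L, p + 9L + stem) # 1-based indices
    perm <- withr::with_seed(as.integer(seed), sample(length(span)))
    ch[span] <- ch[span][perm]
  }
  paste(ch, collapse = "")
}
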