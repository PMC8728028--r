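#' Configuration for the synthetic MPRA library simulator
#'
#' Bundles the generative parameters for [simulate_library()] and
#' [simulate_counts()]. Defaults emulate the study conditions of a
#' reporter-assay 3' UTR library: 160-nt segments, about 22 clones per
#' segment, background GC content around 0.45, a baseline stability of 0.56
#' for motif-free segments, destabilizing ARE/CDE effects monotone in
#' effective length and stem length, and a mild negative GC trend.
#'
#' @param n_segments Number of reference segments.
#' @param frac_are,frac_cde Fractions of reference segments carrying a
#'   planted ARE / CDE (the rest are motif-free background).
#' @param window Segment length in nt.
#' @param gc_target Mean GC fraction of background sequence.
#' @param clones_mean Mean clones per segment (Poisson, minimum 1).
#' @param depth_mean Mean reads per clone per timepoint (Poisson, min 1).
#' @param base_expression,base_stability Latent values for a motif-free
#'   segment at `gc_target`.
#' @param gc_slope_expression,gc_slope_stability Linear GC trend slopes
#'   (latent value change per unit GC, centred at `gc_target`).
#' @param are_effect_expression,are_effect_stability Functions mapping ARE
#'   effective length to an additive latent effect (negative =
#'   destabilizing).
#' @param cde_effect_expression,cde_effect_stability Functions mapping CDE
#'   stem length to an additive latent effect.
#' @param noise_sd Segment-level residual SD (sequence effects beyond the
#'   planted motifs).
#' @param clone_sd Clone-level SD of the latent ratio (technical variation
#'   between lentiviral integrants, beyond read sampling).
#' @param make_mutants Whether to build designed mutant partners.
#' @param n_chromosomes Number of chromosome labels assigned round-robin.
#' @param seed Integer seed (mandatory; the simulation is fully
#'   deterministic given the config).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_segments = 400L,
                       frac_are = 0.5,
                       frac_cde = 0.15,
                       window = 160L,
                       gc_target = 0.45,
                       clones_mean = 22,
                       depth_mean = 100,
                       base_expression = 0.5,
                       base_stability = 0.56,
                       gc_slope_expression = -0.3,
                       gc_slope_stability = -0.3,
                       are_effect_expression = function(eff) pmax(-0.3, -0.010 * eff),
                       are_effect_stability = function(eff) pmax(-0.4, -0.020 * eff),
                       cde_effect_expression = function(stem) -0.02 * stem,
                       cde_effect_stability = function(stem) -0.05 * stem,
                       noise_sd = 0.02,
                       clone_sd = 0.02,
                       make_mutants = TRUE,
                       n_chromosomes = 24L,
                       seed) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  if (gc_target <= 0 || gc_target >= 1) {
    stop("gc_target must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (frac_are + frac_cde > 1) stop("frac_are + frac_cde must be <= 1", call. = FALSE)
  if (depth_mean < 1) stop("depth_mean must be at least 1", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

random_background <- function(n, len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(probs), len, TRUE, prob = probs), collapse = "")
  }, character(1))
}

clamp01 <- function(x, eps = 0.02) pmin(pmax(x, eps), 1 - eps)

#' Simulate a reporter library of segments with planted motifs
#'
#' Generates random-background 160-nt segments at a controlled GC content
#' and plants AREs (periodic AUUUA runs spanning lengths 5-21 and all four
#' registrations, flanked by G guards so the planted run is maximal) and
#' CDEs (UUCYRYGAA cores with reverse-complementary stems of 0-5 bp, flanked
#' by non-pairing guards) into configured fractions of them. Designed mutant
#' partners are built with [mutate_are()] / [mutate_cde()] (CDE mutants
#' alternate between core and shuffle modes). Each segment's latent
#' steady-state expression and stability are the baseline plus the GC trend
#' evaluated at the realized GC, the planted motif effect, and a
#' segment-level residual; chromosome labels are assigned round-robin.
#'
#' @param config A [sim_config()].
#' @return A list with `segments` (annotation tibble: `segment_id`,
#'   `transcript_id`, `chromosome`, `role`, `partner_id`, `sequence`,
#'   `gc_fraction`, `pad_length`) and `truth` (per-segment tibble of the
#'   planted motif inventory and latent `expression`, `stability`, `r0`,
#'   `r4`).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(as.integer(cfg$seed), {
    n <- cfg$n_segments
    type <- sample(c(
      rep("are", round(cfg$frac_are * n)),
      rep("cde", round(cfg$frac_cde * n)),
      rep("background", n)
    )[seq_len(n)])
    chrom <- paste0("chr", c(seq_len(cfg$n_chromosomes)))[
      (seq_len(n) - 1L) %% cfg$n_chromosomes + 1L
    ]
    seqs <- random_background(n, cfg$window, cfg$gc_target)
    motif <- tibble::tibble(
      segment_id = sprintf("seg%04d", seq_len(n)),
      motif = type, motif_start = NA_integer_, motif_length = NA_integer_,
      registration = NA_integer_, effective_length = NA_integer_,
      stem_length = NA_integer_
    )
    for (i in seq_len(n)) {
      if (type[i] == "are") {
        L <- sample(5:21, 1L)
        g <- if (L == 5L) 0L else sample(0:3, 1L)
        core <- paste0("G", periodic_pattern(g, L), "G") # G guards: maximal run
        pos <- sample.int(cfg$window - nchar(core) + 1L, 1L)
        substr(seqs[i], pos, pos + nchar(core) - 1L) <- core
        motif$motif_start[i] <- pos # 0-based start of the run (after guard)
        motif$motif_length[i] <- L
        motif$registration[i] <- g
        motif$effective_length[i] <- L + g
      } else if (type[i] == "cde") {
        stem_n <- sample(0:5, 1L)
        core <- paste0(
          "UU", "C", sample(c("C", "U"), 1L), sample(c("A", "G"), 1L),
          sample(c("C", "U"), 1L), "GAA"
        )
        up <- if (stem_n > 0L) {
          paste(sample(RNA_ALPHABET, stem_n, TRUE), collapse = "")
        } else ""
        down <- if (stem_n > 0L) revcomp_rna(up) else ""
        insert <- paste0("A", up, core, down, "A") # A guards cannot pair
        pos <- sample.int(cfg$window - nchar(insert) + 1L, 1L)
        substr(seqs[i], pos, pos + nchar(insert) - 1L) <- insert
        motif$motif_start[i] <- pos + stem_n # 0-based core start
        motif$stem_length[i] <- stem_n
      }
    }
    refs <- tibble::tibble(
      segment_id = motif$segment_id,
      transcript_id = sprintf("tx%04d", seq_len(n)),
      chromosome = chrom,
      role = "reference",
      partner_id = NA_character_,
      sequence = seqs,
      pad_length = 0L
    )
    segments <- refs
    if (cfg$make_mutants) {
      muts <- refs
      cde_mode <- rep_len(c("core", "shuffle"), n)
      for (i in seq_len(n)) {
        if (type[i] == "are") {
          muts$sequence[i] <- mutate_are(refs$sequence[i], list(
            start = motif$motif_start[i], length = motif$motif_length[i],
            start_registration = motif$registration[i]
          ))
          muts$role[i] <- "are_mutant"
        } else if (type[i] == "cde") {
          muts$sequence[i] <- mutate_cde(
            refs$sequence[i],
            list(core_start = motif$motif_start[i],
                 stem_length = motif$stem_length[i]),
            mode = cde_mode[i], seed = cfg$seed + i
          )
          muts$role[i] <- paste0("cde_", cde_mode[i], "_mutant")
        }
      }
      keep <- muts$role != "reference"
      muts <- muts[keep, ]
      muts$partner_id <- muts$segment_id
      muts$segment_id <- paste0(muts$segment_id, "_mut")
      segments <- dplyr::bind_rows(refs, muts)
    }
    segments$gc_fraction <- gc_fraction(segments$sequence)

    # latent activity: baseline + GC trend + motif effect + residual
    truth <- dplyr::left_join(
      segments[c("segment_id", "role", "partner_id", "chromosome", "gc_fraction")],
      motif,
      by = c(segment_id = "segment_id")
    )
    # mutants: look motif info up via partner, but their effect is removed
    is_mut <- truth$role != "reference"
    pm <- match(sub("_mut$", "", truth$segment_id[is_mut]), motif$segment_id)
    for (col in c("motif_start", "motif_length", "registration",
                  "effective_length", "stem_length")) {
      truth[[col]][is_mut] <- motif[[col]][pm]
    }
    truth$motif[is_mut] <- paste0(motif$motif[pm], "_mutated")
    eff_expr <- numeric(nrow(truth))
    eff_stab <- numeric(nrow(truth))
    ref_rows <- which(!is_mut)
    are_rows <- ref_rows[truth$motif[ref_rows] == "are"]
    cde_rows <- ref_rows[truth$motif[ref_rows] == "cde"]
    eff_expr[are_rows] <- cfg$are_effect_expression(truth$effective_length[are_rows])
    eff_stab[are_rows] <- cfg$are_effect_stability(truth$effective_length[are_rows])
    eff_expr[cde_rows] <- cfg$cde_effect_expression(truth$stem_length[cde_rows])
    eff_stab[cde_rows] <- cfg$cde_effect_stability(truth$stem_length[cde_rows])
    trend_e <- cfg$gc_slope_expression * (truth$gc_fraction - cfg$gc_target)
    trend_s <- cfg$gc_slope_stability * (truth$gc_fraction - cfg$gc_target)
    truth$expression <- clamp01(
      cfg$base_expression + trend_e + eff_expr + rnorm(nrow(truth), 0, cfg$noise_sd)
    )
    truth$stability <- clamp01(
      cfg$base_stability + trend_s + eff_stab + rnorm(nrow(truth), 0, cfg$noise_sd)
    )
    truth$r0 <- truth$expression
    truth$r4 <- clamp01(
      truth$stability * truth$r0 / (1 - truth$stability), eps = 0.01
    )
    list(segments = segments, truth = truth)
  })
}

#' Simulate clone-level counts from latent segment activities
#'
#' For each segment, draws a Poisson number of clones (mean
#' `clones_mean`, minimum 1) carrying unique random 8-mer barcodes. Each
#' clone's latent ratio at each timepoint is the segment's latent ratio plus
#' clone-level Gaussian jitter (`clone_sd`); reads are then split
#' binomially: total reads T ~ Poisson(`depth_mean`) (minimum 1),
#' RNA ~ Binomial(T, r_t), DNA = T - RNA. The binomial read split matches
#' the proportion form of the expression statistic.
#'
#' @param truth Truth tibble from [simulate_library()] (columns
#'   `segment_id`, `r0`, `r4`).
#' @param config The same [sim_config()].
#' @param seed Seed for the count draws; defaults to `config$seed + 1`.
#' @return A clone-count tibble: `segment_id`, `barcode` (`clone_barcode`
#'   duplicate column included for the on-disk format), `dna_t0`, `rna_t0`,
#'   `dna_t4`, `rna_t4`.
#' @export
simulate_counts <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(as.integer(seed), {
    n_clones <- pmax(1L, rpois(nrow(truth), cfg$clones_mean))
    seg <- rep(truth$segment_id, n_clones)
    r0 <- clamp01(rep(truth$r0, n_clones) +
                    rnorm(length(seg), 0, cfg$clone_sd), eps = 0.005)
    r4 <- clamp01(rep(truth$r4, n_clones) +
                    rnorm(length(seg), 0, cfg$clone_sd), eps = 0.005)
    t0 <- pmax(1L, rpois(length(seg), cfg$depth_mean))
    t4 <- pmax(1L, rpois(length(seg), cfg$depth_mean))
    rna0 <- rbinom(length(seg), t0, r0)
    rna4 <- rbinom(length(seg), t4, r4)
    codes <- sample.int(4L^8L, length(seg)) - 1L # unique base-4 codes
    barcode <- vapply(codes, function(v) {
      paste(RNA_ALPHABET[(v %/% 4L^(7:0)) %% 4L + 1L], collapse = "")
    }, character(1))
    tibble::tibble(
      segment_id = seg,
      barcode = barcode,
      dna_t0 = t0 - rna0,
      rna_t0 = rna0,
      dna_t4 = t4 - rna4,
      rna_t4 = rna4
    )
  })
}

#' Simulate a full dataset (library + counts)
#'
#' @param config A [sim_config()].
#' @return A list with `segments`, `truth`, and `counts`.
#' @export
simulate_dataset <- function(config) {
  lib <- simulate_library(config)
  lib$counts <- simulate_counts(lib$truth, config)
  lib
}
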