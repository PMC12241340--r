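#' Configuration for the transcriptome / read-set simulator
#'
#' Defines the study-like conditions under which synthetic data are drawn:
#' a mixture of circular and linear transcripts, 2 x 75 bp paired-end reads,
#' and an RNase R treatment that divides the sampling mass of linear
#' molecules by `depletion_factor` while multiplying circular mass by
#' `circ_retention`.
#'
#' @param n_circ Number of circular transcripts (>= 1).
#' @param n_linear Number of linear transcripts (>= 0).
#' @param length_range Integer interval (nt) for transcript lengths; the
#'   lower bound must be >= 31 or the backsplice junction is undefined.
#' @param n_reads Number of read pairs (fragments) to simulate.
#' @param read_len Read length in nt (default 75, as in 2 x 75 bp
#'   sequencing); must be >= 31 so a read can contain a junction 31-mer.
#' @param inner_dist Fixed inner distance between mates, nt.
#' @param circ_frac Fraction of untreated read mass of circular origin, in
#'   (0, 1]. circRNAs are a minor component of rRNA-depleted total-RNA
#'   libraries; the default 0.05 reflects that.
#' @param depletion_factor Divisor applied to linear sampling mass under
#'   RNase R treatment (>= 1). The effective magnitude of RNase R depletion
#'   is a free parameter of the simulator.
#' @param circ_retention Multiplier applied to circular mass under
#'   treatment, in (0, 1].
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_circ, n_linear, length_range = c(300L, 1500L),
                       n_reads = 100000L, read_len = 75L, inner_dist = 50L,
                       circ_frac = 0.05, depletion_factor = 50,
                       circ_retention = 1, seed = 1L) {
  stopifnot(n_circ >= 1L, n_linear >= 0L, n_reads >= 0L,
            length(length_range) == 2L, length_range[1] <= length_range[2],
            read_len >= 31L, inner_dist >= 0L,
            circ_frac > 0, circ_frac <= 1,
            depletion_factor >= 1, circ_retention > 0, circ_retention <= 1)
  if (length_range[1] < 31L)
    stop("length_range lower bound must be >= 31 nt: ",
         "the backsplice junction is undefined for shorter transcripts")
  structure(list(n_circ = as.integer(n_circ), n_linear = as.integer(n_linear),
                 length_range = as.integer(length_range),
                 n_reads = as.integer(n_reads), read_len = as.integer(read_len),
                 inner_dist = as.integer(inner_dist), circ_frac = circ_frac,
                 depletion_factor = depletion_factor,
                 circ_retention = circ_retention, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a mixed circular/linear transcriptome
#'
#' Sequences are drawn uniformly over A/C/G/T with lengths uniform over
#' `cfg$length_range`. Relative abundances are drawn from a symmetric
#' Dirichlet with concentration 5 (moderate inter-transcript variability,
#' coefficient of variation ~0.45) independently within the circular and
#' the linear class, and recorded as ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_transcriptome`: list with `circ` and `linear` (named
#'   sequence vectors, circBank-style `hsa_circ_` ids and `lin_` ids),
#'   `abund_circ`, `abund_linear` (named, each summing to 1), and `cfg`.
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    circ_ids <- sprintf("hsa_circ_%07d", seq_len(cfg$n_circ))
    lin_ids <- if (cfg$n_linear > 0L)
      sprintf("lin_%05d", seq_len(cfg$n_linear)) else character(0)
    lr <- cfg$length_range
    rand_len <- function(n) lr[1] + sample.int(lr[2] - lr[1] + 1L, n, TRUE) - 1L
    circ <- random_dna(cfg$n_circ, rand_len(cfg$n_circ))
    names(circ) <- circ_ids
    linear <- if (cfg$n_linear > 0L) {
      s <- random_dna(cfg$n_linear, rand_len(cfg$n_linear))
      names(s) <- lin_ids
      s
    } else structure(character(0), names = character(0))
    ab_c <- rgamma(cfg$n_circ, 5); ab_c <- ab_c / sum(ab_c)
    names(ab_c) <- circ_ids
    ab_l <- if (cfg$n_linear > 0L) {
      a <- rgamma(cfg$n_linear, 5); a / sum(a)
    } else numeric(0)
    names(ab_l) <- lin_ids
    structure(list(circ = circ, linear = linear,
                   abund_circ = ab_c, abund_linear = ab_l, cfg = cfg),
              class = "sim_transcriptome")
  })
}

#' Simulate a paired-end read set, with or without RNase R treatment
#'
#' Fragments of length `2 * read_len + inner_dist` are drawn from molecules
#' chosen by their sampling mass. Untreated mass is
#' `circ_frac * abund_circ` for circles and `(1 - circ_frac) * abund_linear`
#' for linear molecules; under treatment linear mass is divided by
#' `depletion_factor` and circular mass multiplied by `circ_retention`
#' before renormalization, so the expected circular/linear odds rise by
#' exactly `depletion_factor / circ_retention`. Circular templates are
#' sampled with wrap-around (the sequence is tiled and a start position
#' uniform over the circumference is drawn), so a fraction of circular reads
#' spans the backsplice junction; linear templates use a uniform start in
#' `[1, L - fragment + 1]`. Mate 1 is the fragment 5' end, mate 2 the
#' reverse complement of its 3' end (FR orientation).
#'
#' @param tx A [simulate_transcriptome()] result.
#' @param treated Logical: apply the RNase R mass model?
#' @param seed Optional integer seed; defaults to `cfg$seed + treated`.
#' @return A list with
#'   \describe{
#'     \item{reads}{a `read_set`: list with `read1`, `read2` (character
#'       vectors), `sample_id`, `treated`.}
#'     \item{truth}{realized per-molecule fragment counts, the expected class
#'       mass used, per-fragment origin ids, and a logical `spans_junction`
#'       for mate 1 of circular fragments.}
#'   }
#' @export
simulate_read_set <- function(tx, treated = FALSE, seed = NULL) {
  stopifnot(inherits(tx, "sim_transcriptome"))
  cfg <- tx$cfg
  if (is.null(seed)) seed <- cfg$seed + as.integer(treated)
  frag_len <- 2L * cfg$read_len + cfg$inner_dist
  if (length(tx$linear) && min(nchar(tx$linear)) < frag_len)
    stop("shortest linear transcript (", min(nchar(tx$linear)),
         " nt) is shorter than the fragment length (", frag_len, " nt)")

  w_circ <- cfg$circ_frac * tx$abund_circ
  w_lin <- if (length(tx$linear)) (1 - cfg$circ_frac) * tx$abund_linear
           else numeric(0)
  if (treated) {
    w_lin <- w_lin / cfg$depletion_factor
    w_circ <- w_circ * cfg$circ_retention
  }
  w <- c(w_circ, w_lin)
  w <- w / sum(w)
  mol_ids <- names(w)
  is_circ <- c(rep(TRUE, length(w_circ)), rep(FALSE, length(w_lin)))

  with_seed(seed, {
    n <- cfg$n_reads
    read1 <- character(n); read2 <- character(n)
    origin <- character(0); spans <- logical(n)
    if (n > 0L) {
      idx <- sample.int(length(w), n, replace = TRUE, prob = w)
      origin <- mol_ids[idx]
      seqs <- c(tx$circ, tx$linear)[idx]
      L <- nchar(seqs)
      circ_i <- is_circ[idx]
      start <- integer(n)
      # circular: start uniform over circumference, template tiled
      if (any(circ_i)) {
        Lc <- L[circ_i]
        start[circ_i] <- floor(runif(sum(circ_i)) * Lc) + 1L
        reps <- ceiling((frag_len - 1L) / Lc) + 1L
        seqs[circ_i] <- strrep(seqs[circ_i], reps)
      }
      if (any(!circ_i)) {
        Ll <- L[!circ_i]
        start[!circ_i] <- floor(runif(sum(!circ_i)) * (Ll - frag_len + 1L)) + 1L
      }
      frag <- unname(substr(seqs, start, start + frag_len - 1L))
      read1 <- substr(frag, 1L, cfg$read_len)
      read2 <- revcomp(substr(frag, frag_len - cfg$read_len + 1L, frag_len))
      # mate 1 spans the backsplice iff it crosses the circumference boundary
      spans <- circ_i & (start + cfg$read_len - 1L > L)
    }
    counts <- structure(integer(length(mol_ids)), names = mol_ids)
    if (n > 0L) {
      tb <- table(factor(origin, levels = mol_ids))
      counts[] <- as.integer(tb)
    }
    reads <- structure(list(read1 = read1, read2 = read2,
                            sample_id = if (treated) "treated" else "control",
                            treated = treated),
                       class = "read_set")
    truth <- list(counts = counts, mass = w, origin = origin,
                  spans_junction = spans,
                  depletion_factor = if (treated) cfg$depletion_factor else 1,
                  circ_retention = if (treated) cfg$circ_retention else 1)
    list(reads = reads, truth = truth)
  })
}

#' Write a read set as paired FASTQ files
#'
#' Constant quality (Q40, 'I') is emitted; the simulator has no
#' sequencing-error model. Files are named `<prefix>_R1.fastq` and
#' `<prefix>_R2.fastq`.
#'
#' @param rs A `read_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the sample id.
#' @return Character vector of the two paths, invisibly.
#' @export
write_read_set <- function(rs, dir, prefix = rs$sample_id) {
  stopifnot(inherits(rs, "read_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_R1.fastq", "_R2.fastq")))
  ids <- sprintf("%s_frag_%06d", prefix, seq_along(rs$read1))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(if (m == 1) rs$read1 else rs$read2)
    names(seqs) <- paste0(ids, "/", m)
    qual <- Biostrings::PhredQuality(strrep("I", Biostrings::width(seqs)))
    q <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
    Biostrings::writeQualityScaledXStringSet(q, paths[m])
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read set
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files (gz accepted).
#' @param sample_id Sample label.
#' @param treated Logical treatment flag carried on the object.
#' @return A `read_set`.
#' @export
read_fastq_pair <- function(r1, r2, sample_id = "sample", treated = FALSE) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2))
    stop("mate files differ in read count: ", length(s1), " vs ", length(s2))
  structure(list(read1 = as.character(s1), read2 = as.character(s2),
                 sample_id = sample_id, treated = treated),
            class = "read_set")
}

#' Configuration for the survival-cohort simulator
#'
#' @param n_patients Cohort size (default 96, a typical FFPE breast-cancer
#'   cohort size); must be >= 2.
#' @param n_features Number of expression features (circRNAs).
#' @param effect Named numeric vector of planted log-hazard coefficients
#'   (per standard deviation of log2 expression); names are feature ids
#'   (`feat_0001` style) or indices.
#' @param baseline_hazard Baseline event rate per month. The default 0.015
#'   gives roughly 80% cumulative relapse probability over the 120-month
#'   window for a no-effect patient.
#' @param censor_rate Independent censoring rate per month (0 = none).
#' @param follow_up_cap Administrative censoring time in months (default
#'   120, the ten-year relapse-free-survival window).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 96L, n_features = 200L,
                          effect = numeric(0), baseline_hazard = 0.015,
                          censor_rate = 0.003, follow_up_cap = 120,
                          seed = 1L) {
  stopifnot(n_patients >= 2L, n_features >= 1L, follow_up_cap > 0,
            baseline_hazard > 0, censor_rate >= 0)
  n_features <- as.integer(n_features)
  if (length(effect)) {
    if (is.null(names(effect)))
      names(effect) <- sprintf("feat_%04d", as.integer(seq_along(effect)))
    stopifnot(all(grepl("^feat_", names(effect))))
  }
  structure(list(n_patients = as.integer(n_patients), n_features = n_features,
                 effect = effect, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, follow_up_cap = follow_up_cap,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate an expression matrix and survival cohort under proportional hazards
#'
#' log2 expression is Gaussian per feature (mean 5, sd 2, a log-normal
#' abundance model); each patient's hazard is
#' `baseline_hazard * exp(sum(beta * z))` where `z` is the per-feature
#' z-score of log2 expression and `beta` the planted coefficients. Event
#' times are exponential with that hazard; censoring is an independent
#' exponential; times are capped at `follow_up_cap` with `event = 0` at the
#' cap. Age, grade and molecular subtype are drawn as effect-free
#' covariates.
#'
#' @param cfg A [cohort_config()].
#' @return List with `expr` (features x patients matrix of log2 expression),
#'   `clinical` (data.frame: `sample_id`, `time_months`, `event`, `age`,
#'   `grade`, `subtype`), and `truth` (planted betas and per-patient hazard).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (length(cfg$effect) &&
      any(!names(cfg$effect) %in% sprintf("feat_%04d", seq_len(cfg$n_features))))
    stop("planted effect ids outside the simulated feature set")
  with_seed(cfg$seed, {
    n <- cfg$n_patients; p <- cfg$n_features
    feat_ids <- sprintf("feat_%04d", seq_len(p))
    ids <- sprintf("BC%04d", seq_len(n))
    expr <- matrix(rnorm(p * n, mean = 5, sd = 2), nrow = p,
                   dimnames = list(feat_ids, ids))
    lp <- numeric(n)
    if (length(cfg$effect)) {
      z <- t(scale(t(expr[names(cfg$effect), , drop = FALSE])))
      lp <- as.numeric(crossprod(z, cfg$effect))
    }
    hazard <- cfg$baseline_hazard * exp(lp)
    t_event <- rexp(n, hazard)
    t_cens <- if (cfg$censor_rate > 0) rexp(n, cfg$censor_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens, cfg$follow_up_cap)
    event <- as.integer(t_event <= pmin(t_cens, cfg$follow_up_cap))
    clinical <- data.frame(
      sample_id = ids,
      time_months = time,
      event = event,
      age = pmin(pmax(round(rnorm(n, 55, 12)), 25), 90),
      grade = sample(1:3, n, TRUE, prob = c(0.2, 0.45, 0.35)),
      subtype = sample(c("LuminalA", "LuminalB", "HER2", "TNBC"), n, TRUE,
                       prob = c(0.4, 0.25, 0.15, 0.2)),
      stringsAsFactors = FALSE)
    truth <- list(beta = cfg$effect, hazard = hazard,
                  t_event = t_event, cfg = cfg)
    list(expr = expr, clinical = clinical, truth = truth)
  })
}

#' Write a simulated clinical table as TSV
#'
#' @param clinical The `clinical` data.frame from [simulate_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
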