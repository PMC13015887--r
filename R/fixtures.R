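# Seeded synthetic-data generators and file IO. Every other module is
# testable from these generators alone; no external data is required.

.BASES <- c("A", "C", "G", "T")

# restore the caller's RNG state on exit
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

.random_seq <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, len, replace = TRUE, prob = p), collapse = "")
}

# random sequence with an exact G+C count (shuffled composition vector)
.balanced_seq <- function(len, gc = 0.5) {
  ngc <- round(len * gc)
  sample(c(sample(c("G", "C"), ngc, replace = TRUE),
           sample(c("A", "T"), len - ngc, replace = TRUE)))
}

# Design a GC-balanced sequence toward a target duplex dG, the way primers
# are designed in practice: pick a balanced random sequence, tune its
# LENGTH (base insertion/deletion at the 5' end) until the free energy
# brackets the target, then refine with single-base substitutions that
# keep the composition within the gc_band.
.design_seq <- function(target_dG, conditions, params,
                        length_range = c(8, 30), gc_band = c(0.35, 0.65),
                        max_iter = 200, tol = 0.5) {
  dg_of <- function(b) duplex_thermo(paste(b, collapse = ""),
                                     conditions, params)$dG
  gc_mid <- mean(gc_band)
  s <- .balanced_seq(length_range[1], gc_mid)
  # extend the 5' end (keeping composition on target) until at least as
  # stable as the requested dG, then trim back
  while (dg_of(s) > target_dG && length(s) < length_range[2]) {
    pool <- if (mean(s %in% c("G", "C")) < gc_mid) c("G", "C") else c("A", "T")
    s <- c(sample(pool, 1), s)
  }
  while (dg_of(s) < target_dG - 0.5 && length(s) > length_range[1]) {
    s <- s[-1]
  }
  in_band <- function(b) {
    gc <- mean(b %in% c("G", "C"))
    gc >= gc_band[1] && gc <= gc_band[2]
  }
  best <- abs(dg_of(s) - target_dG)
  for (i in seq_len(max_iter)) {
    if (best <= tol * 0.4 && in_band(s)) break
    cand <- s
    pos <- sample.int(length(cand), 1)
    cand[pos] <- sample(setdiff(.BASES, cand[pos]), 1)
    if (!in_band(cand)) next
    sc <- abs(dg_of(cand) - target_dG)
    if (sc < best || !in_band(s)) {
      s <- cand
      best <- sc
    }
  }
  paste(s, collapse = "")
}

#' Generate a seeded primer panel
#'
#' Designs `n_primers` random binding regions whose duplex free energies
#' tile a requested window uniformly, by greedy base substitution toward
#' per-primer targets.  Four tag sequences of differing GC content, each
#' designed to the requested tag free energy, are attached as the
#' `"tags"` attribute.  Fixed seed implies identical output.
#'
#' @param n_primers Number of primers.
#' @param dg_range Window of target binding free energies `c(lo, hi)`,
#'   kcal/mol, tiled uniformly.
#' @param length_range Admissible binding-region length range, nt; the
#'   designer tunes length (5' insertion/deletion) to reach each target,
#'   the way primer free energies are modulated in practice.
#' @param gc_band Admissible GC-fraction band for designed sequences.
#' @param tag_dG Design target for the four default tags, kcal/mol.
#' @param conditions,params Thermodynamic engine settings used for design.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param tol Maximum accepted |achieved - target| deviation, kcal/mol;
#'   primers still off-target after the search are flagged in the
#'   `achieved` column.
#' @param fasta Optional path: write the panel as FASTA.
#' @return data.frame with columns `id`, `sequence`, `length`, `gc`,
#'   `target_dG`, `dG`, `achieved`; attribute `tags` is a data.frame of
#'   the four designed tags (`sequence`, `gc`, `dG`).
#' @examples
#' panel <- generate_primer_panel(5, seed = 1)
#' attr(panel, "tags")
#' @export
generate_primer_panel <- function(n_primers = 100, dg_range = c(-13, -5),
                                  length_range = c(8, 30),
                                  gc_band = c(0.35, 0.65), tag_dG = -12,
                                  conditions = ref_protocol()$conditions,
                                  params = nn_params(), seed = NULL,
                                  tol = 0.5, fasta = NULL) {
  stopifnot(n_primers >= 1, dg_range[1] < dg_range[2])
  .with_seed(seed, {
    targets <- seq(dg_range[1], dg_range[2], length.out = n_primers)
    rows <- lapply(seq_len(n_primers), function(i) {
      s <- .design_seq(targets[i], conditions, params,
                       length_range = length_range, gc_band = gc_band,
                       tol = tol)
      dg <- duplex_thermo(s, conditions, params)$dG
      gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
      data.frame(id = sprintf("primer_%03d", i), sequence = s,
                 length = nchar(s), gc = gc, target_dG = targets[i], dG = dg,
                 achieved = abs(dg - targets[i]) <= tol)
    })
    panel <- do.call(rbind, rows)
    tag_gc_bands <- list(c(0.15, 0.35), c(0.35, 0.5), c(0.5, 0.65),
                         c(0.65, 0.85))
    tags <- do.call(rbind, lapply(seq_along(tag_gc_bands), function(i) {
      s <- .design_seq(tag_dG, conditions, params,
                       gc_band = tag_gc_bands[[i]])
      data.frame(id = sprintf("tag_%d", i), sequence = s,
                 gc = sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s),
                 dG = duplex_thermo(s, conditions, params)$dG)
    }))
    attr(panel, "tags") <- tags
    if (!is.null(fasta)) write_fasta(stats::setNames(panel$sequence, panel$id), fasta)
    panel
  })
}

#' Generate a synthetic amplification-record dataset
#'
#' Stands in for an experimental qPCR Ct table: for every primer x
#' temperature x time x tag combination the kinetic simulator produces a
#' Ct value, Gaussian noise of `noise_sd` cycles is added per replicate,
#' values are capped at 50 (non-amplifying reactions), and the median of
#' the replicates is taken as the record's Ct (the replicate values are
#' kept alongside).
#'
#' @param panel A panel from [generate_primer_panel()] (or a data.frame
#'   with a `sequence` column).
#' @param temperatures,times Condition grids (degrees C, seconds).
#' @param tag_flags Logical vector: which tag configurations to emit
#'   (`FALSE` = conventional primer, `TRUE` = tag primer at `tag_dG`).
#' @param tag_dG Tag free energy used for tagged records, kcal/mol.
#' @param noise_sd Gaussian Ct noise per replicate, cycles.
#' @param replicates Number of replicates (median-aggregated).
#' @param protocol Base protocol; temperature/time overridden per record.
#' @param detection_threshold Ct detection threshold, copies.
#' @param cap Ct cap for non-amplifying reactions.
#' @param seed Integer seed.
#' @param params NN parameter set.
#' @return data.frame with one row per condition: `id`, `sequence`,
#'   `tag` (logical), `tag_dG`, `temperature`, `time`, replicate columns
#'   `ct_rep1..k`, `ct` (median), `censored` (Ct at cap).
#' @export
generate_ct_dataset <- function(panel,
                                temperatures = c(57, 60, 63),
                                times = c(30, 120),
                                tag_flags = c(FALSE, TRUE),
                                tag_dG = -12, noise_sd = 1, replicates = 3,
                                protocol = ref_protocol(),
                                detection_threshold = 1e10, cap = 50,
                                seed = NULL, params = nn_params()) {
  .with_seed(seed, {
    grid <- expand.grid(row = seq_len(nrow(panel)),
                        temperature = temperatures, time = times,
                        tag = tag_flags)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      conds <- protocol$conditions
      conds$temperature <- g$temperature
      conds$extension_time <- g$time
      s <- panel$sequence[g$row]
      dg <- duplex_thermo(s, conds, params)$dG
      tg <- if (g$tag) tag_dG else 0
      sim <- run_pcr(pa_primer(dG_binding = dg, dG_tag = tg),
                     cycles = cap, conditions = conds,
                     anneal = "equilibrium")
      ct0 <- ct_from_sim(sim, detection_threshold, cap = cap)
      reps <- pmin(ct0 + stats::rnorm(replicates, 0, noise_sd), cap)
      reps <- pmax(reps, 0.01)
      rec <- data.frame(id = panel$id[g$row], sequence = s,
                        tag = g$tag, tag_dG = tg,
                        temperature = g$temperature, time = g$time)
      for (r in seq_len(replicates)) rec[[paste0("ct_rep", r)]] <- reps[r]
      rec$ct <- stats::median(reps)
      rec$censored <- rec$ct >= cap
      rec
    })
    do.call(rbind, rows)
  })
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read an amplification-record CSV
#'
#' Validates the fixed schema used throughout the package (UTF-8, comma
#' separated, header row, '.' decimal separator).
#'
#' @param path CSV path.
#' @return data.frame of records.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "tag", "temperature", "time", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("record CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$tag <- as.logical(df$tag)
  df
}

#' Write an amplification-record CSV
#'
#' @param records data.frame of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
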