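# Application simulators: multi-template sequencing read allocation with
# fusion detection limits, and tiered DNA-data-storage random access with
# majority-vote decoding.

#' Sequencing read fractions of a multi-template pool
#'
#' After `cycles` cycles of amplification, template `i` with relative
#' expression `ratio_i` and equivalent amplification efficiency `e_i`
#' contributes reads in proportion to `ratio_i * (1 + e_i)^cycles`.  With
#' equal efficiencies this reduces to expression-ratio normalization;
#' tuning efficiencies against the ratios equalizes representation.
#'
#' @param pool data.frame with columns `ratio` (> 0, relative expression)
#'   and `efficiency` (per-cycle, in `[0, 1]`); at least 2 templates.
#' @param cycles Amplification cycle count.
#' @return Numeric vector of read fractions (sums to 1), named after
#'   `pool$template` when present.
#' @examples
#' # 26-fold reference:target disparity, equal efficiencies
#' read_fractions(data.frame(ratio = c(26, 1), efficiency = c(1, 1)))
#' @export
read_fractions <- function(pool, cycles = 0) {
  stopifnot(is.data.frame(pool), nrow(pool) >= 2)
  if (any(pool$ratio <= 0)) stop("ratios must be > 0")
  if (any(pool$efficiency < 0 | pool$efficiency > 1)) {
    stop("efficiencies must lie in [0, 1]")
  }
  w <- pool$ratio * (1 + pool$efficiency)^cycles
  f <- w / sum(w)
  if ("template" %in% names(pool)) names(f) <- pool$template
  f
}

#' Minimum detectable fusion frequency
#'
#' A fusion at frequency `f` in a gene capturing `target_fraction` of all
#' reads yields on average `depth * target_fraction * f` supporting
#' reads.  The detection rule is `expected supporting reads >=
#' threshold` (default 5); the limit is the smallest candidate frequency
#' satisfying it.  A binomial Monte-Carlo mode is also provided, calling
#' a frequency detectable when at least `power` of simulated assays reach
#' `threshold` supporting reads.
#'
#' @param depth Total sequencing depth, reads (>= 1).
#' @param frequencies Candidate fusion frequencies (fractions), sorted
#'   ascending.
#' @param target_fraction Fraction of reads captured by the target gene.
#' @param threshold Minimum supporting reads (>= 1).
#' @param mode `"expected"` (default) or `"binomial"`.
#' @param power Required detection probability in binomial mode.
#' @param nsim Simulated assays per frequency in binomial mode.
#' @param seed Seed for binomial mode.
#' @return The smallest detectable frequency, or `NA` (with a
#'   `"none detectable"` message attribute) if no candidate qualifies.
#' @examples
#' detection_limit(1e4, c(3e-4, 1e-3, 1e-2, 1e-1), target_fraction = 1/27)
#' @export
detection_limit <- function(depth, frequencies, target_fraction,
                            threshold = 5,
                            mode = c("expected", "binomial"),
                            power = 0.95, nsim = 2000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(depth >= 1, threshold >= 1,
            target_fraction > 0, target_fraction <= 1)
  if (is.unsorted(frequencies)) stop("frequencies must be sorted ascending")
  detected <- if (mode == "expected") {
    depth * target_fraction * frequencies >= threshold
  } else {
    .with_seed(seed, vapply(frequencies, function(f) {
      hits <- stats::rbinom(nsim, size = round(depth),
                            prob = target_fraction * f)
      mean(hits >= threshold) >= power
    }, logical(1)))
  }
  if (!any(detected)) {
    out <- NA_real_
    attr(out, "message") <- "none detectable"
    return(out)
  }
  frequencies[which(detected)[1]]
}

# ---- DNA data storage --------------------------------------------------

.BITS2BASE <- c("00" = "A", "01" = "C", "10" = "G", "11" = "T")
.BASE2BITS <- stats::setNames(names(.BITS2BASE), .BITS2BASE)

.bytes_to_dna <- function(bytes) {
  bits <- as.integer(rawToBits(bytes))      # little-endian per byte
  pairs <- matrix(bits, nrow = 2)
  idx <- pairs[1, ] * 2L + pairs[2, ] + 1L  # 00,01,10,11 -> 1..4
  paste(c("A", "C", "G", "T")[idx], collapse = "")
}

.dna_to_bytes <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(bases, c("A", "C", "G", "T")) - 1L
  bits <- as.vector(rbind(idx %/% 2L, idx %% 2L))
  packBits(as.raw(bits), type = "raw")
}

.int_to_address <- function(i, width) {
  # base-4 big-endian, zero-indexed
  digits <- integer(width)
  x <- i
  for (k in width:1) {
    digits[k] <- x %% 4L
    x <- x %/% 4L
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

.address_to_int <- function(addr) {
  d <- match(strsplit(addr, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  sum(d * 4L^(rev(seq_along(d)) - 1L))
}

# deterministic synthetic primer pairs for archives without a user table
default_primer_table <- function(n_files, length = 20) {
  pat <- c("ACGT", "CAGT", "GTCA", "TGAC", "AGCT", "CTAG", "GACT", "TCGA")
  fwd <- vapply(seq_len(n_files), function(i) {
    core <- .int_to_address(i - 1L, 4)
    paste0(strrep(pat[(i - 1) %% length(pat) + 1], 3), "GG", core,
           strrep("A", length - 18))
  }, character(1))
  rev <- vapply(seq_len(n_files), function(i) {
    core <- .int_to_address(i - 1L, 4)
    paste0(strrep(pat[(i) %% length(pat) + 1], 3), "CC", core,
           strrep("T", length - 18))
  }, character(1))
  data.frame(file = paste0("file_", seq_len(n_files)),
             fwd = substr(fwd, 1, length), rev = substr(rev, 1, length))
}

#' Encode byte files into an addressed oligo archive
#'
#' Each file is divided into fixed-size payload blocks, every block gets a
#' unique in-file address, payload bytes are mapped to DNA with a 2-bit
#' per-base codec, and the file's primer pair is appended to both ends:
#' `oligo = FP + address + payload + RP`.  The mapping is deterministic.
#'
#' @param files Named list of raw vectors (file contents).
#' @param block_size Payload bytes per block.
#' @param primer_table data.frame with columns `file`, `fwd`, `rev` (one
#'   orthogonal pair per file); a deterministic synthetic table is
#'   generated when omitted.
#' @param address_width Address length in bases; computed as
#'   `ceil(log4(max blocks))` when omitted.  Supplying a width too small
#'   for the block count is an address-space overflow and is rejected.
#' @return An object of class `oligo_archive`: list with `oligos`
#'   (data.frame: `file`, `address`, `payload`, `sequence`), `schema`
#'   (primer table, block size, address width, per-file block counts and
#'   byte lengths).
#' @export
encode_archive <- function(files, block_size = 16, primer_table = NULL,
                           address_width = NULL) {
  if (!length(files) || is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("files must be a non-empty named list of raw vectors")
  }
  if (is.null(primer_table)) {
    primer_table <- default_primer_table(length(files))
    primer_table$file <- names(files)
  }
  stopifnot(all(names(files) %in% primer_table$file))
  n_blocks <- vapply(files, function(b) ceiling(length(b) / block_size),
                     numeric(1))
  need_width <- max(1, ceiling(log(max(n_blocks), base = 4)))
  if (is.null(address_width)) address_width <- need_width
  if (4^address_width < max(n_blocks)) {
    stop("address space overflow: ", max(n_blocks), " blocks need width ",
         need_width, " but address_width = ", address_width)
  }
  oligos <- do.call(rbind, lapply(names(files), function(fn) {
    bytes <- files[[fn]]
    nb <- n_blocks[[fn]]
    pr <- primer_table[primer_table$file == fn, ][1, ]
    do.call(rbind, lapply(seq_len(nb), function(i) {
      lo <- (i - 1) * block_size + 1
      hi <- min(i * block_size, length(bytes))
      block <- bytes[lo:hi]
      if (length(block) < block_size) {       # zero-pad the tail block
        block <- c(block, as.raw(rep(0, block_size - length(block))))
      }
      addr <- .int_to_address(i - 1L, address_width)
      payload <- .bytes_to_dna(block)
      data.frame(file = fn, address = addr, payload = payload,
                 sequence = paste0(pr$fwd, addr, payload, pr$rev))
    }))
  }))
  obj <- list(
    oligos = oligos,
    schema = list(primer_table = primer_table, block_size = block_size,
                  address_width = address_width,
                  n_blocks = as.list(n_blocks),
                  byte_length = lapply(files, length))
  )
  class(obj) <- "oligo_archive"
  obj
}

#' Simulate random access (selective amplification + sequencing)
#'
#' Draws `total_reads` reads multinomially from the archive's oligos with
#' per-oligo weights proportional to `(1 + e_file)^cycles`, where
#' `e_file` is the amplification efficiency assigned to the oligo's file
#' primer pair.  Optional uniform per-base substitution noise emulates
#' sequencing error.
#'
#' @param archive An `oligo_archive`.
#' @param per_file_efficiency Named numeric vector (one entry per file),
#'   per-cycle amplification efficiency in `[0, 1]`.
#' @param cycles Access-PCR cycle count (default 12).
#' @param total_reads Number of reads to draw.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution probability.
#' @return Character vector of read sequences.
#' @export
simulate_access <- function(archive, per_file_efficiency, cycles = 12,
                            total_reads = 1e4, seed = 1, error_rate = 0) {
  stopifnot(inherits(archive, "oligo_archive"), total_reads >= 1)
  ol <- archive$oligos
  e <- per_file_efficiency[ol$file]
  if (any(is.na(e))) stop("per_file_efficiency must name every file")
  w <- (1 + e)^cycles
  .with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, size = total_reads,
                                         prob = w / sum(w)))
    reads <- rep(ol$sequence, counts)
    if (error_rate > 0 && length(reads)) {
      reads <- vapply(reads, function(r) {
        b <- strsplit(r, "", fixed = TRUE)[[1]]
        hit <- stats::runif(length(b)) < error_rate
        if (any(hit)) {
          b[hit] <- vapply(b[hit],
                           function(x) sample(setdiff(.BASES, x), 1), "")
        }
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    reads
  })
}

#' Decode an accessed archive by majority vote
#'
#' Reads are validated by exact primer match (assigning them to files),
#' the address and payload regions are extracted, payloads are grouped by
#' address, and for each address the most frequent payload is retained
#' provided it reaches `occurrence_threshold` reads (ties broken toward
#' the lexicographically smallest payload).  Unrecovered blocks are
#' filled with the declared blank byte so file structure is preserved.
#'
#' @param reads Character vector of read sequences.
#' @param schema The `schema` element of an `oligo_archive`.
#' @param occurrence_threshold Minimum reads supporting the winning
#'   payload (default 2).
#' @param blank Byte used for unrecovered blocks.
#' @return List with `files` (named list of raw vectors), `accuracy`
#'   (named vector: fraction of blocks recovered exactly, requires
#'   `reference` when accuracy against truth is wanted) and
#'   `block_recovered` (per-file logical vectors).  When the original
#'   archive is supplied as `reference`, `accuracy` is computed against
#'   its payloads; otherwise it is the fraction of blocks passing the
#'   occurrence threshold.
#' @param reference Optional `oligo_archive` holding ground truth.
#' @export
decode_archive <- function(reads, schema, occurrence_threshold = 2,
                           blank = as.raw(0), reference = NULL) {
  pt <- schema$primer_table
  aw <- schema$address_width
  payload_len <- schema$block_size * 4
  out_files <- list()
  accuracy <- numeric(0)
  recovered <- list()
  for (fn in pt$file) {
    pr <- pt[pt$file == fn, ][1, ]
    nb <- schema$n_blocks[[fn]]
    flen <- nchar(pr$fwd)
    rlen <- nchar(pr$rev)
    expect_len <- flen + aw + payload_len + rlen
    hits <- reads[startsWith(reads, pr$fwd) & endsWith(reads, pr$rev) &
                    nchar(reads) == expect_len]
    addr <- substr(hits, flen + 1, flen + aw)
    payload <- substr(hits, flen + aw + 1, flen + aw + payload_len)
    blocks <- vector("list", nb)
    got <- logical(nb)
    if (length(hits)) {
      by_addr <- split(payload, addr)
      for (a in names(by_addr)) {
        i <- .address_to_int(a) + 1L
        if (i < 1 || i > nb) next
        tab <- table(by_addr[[a]])
        best <- max(tab)
        if (best >= occurrence_threshold) {
          winner <- sort(names(tab)[tab == best])[1]
          blocks[[i]] <- winner
          got[i] <- TRUE
        }
      }
    }
    blank_block <- rep(blank, schema$block_size)
    bytes <- do.call(c, lapply(seq_len(nb), function(i) {
      if (got[i]) .dna_to_bytes(blocks[[i]]) else blank_block
    }))
    bytes <- bytes[seq_len(schema$byte_length[[fn]])]
    out_files[[fn]] <- bytes
    recovered[[fn]] <- got
    accuracy[fn] <- if (!is.null(reference)) {
      truth <- reference$oligos[reference$oligos$file == fn, ]
      truth <- truth[order(vapply(truth$address, .address_to_int, 0)), ]
      mean(vapply(seq_len(nb), function(i) {
        got[i] && identical(blocks[[i]], truth$payload[i])
      }, logical(1)))
    } else mean(got)
  }
  list(files = out_files, accuracy = accuracy, block_recovered = recovered)
}
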