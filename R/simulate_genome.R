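DNA_BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

mutate_protospacer <- function(seq, n_mismatch) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_mismatch)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Simulate a genome with planted guide RNA target sites
#'
#' Builds random ACGT contigs, plants each guide exactly once with zero
#' mismatches plus an NGG PAM, and plants `n_planted_offtargets` additional
#' copies carrying 1..`max_planted_mismatches` protospacer substitutions,
#' each on a random strand at a non-overlapping position.  A random subset
#' of planted sites is marked as a "regulatory" feature in the BED track.
#'
#' @param n_contigs,contig_length genome shape; `contig_length >= 100`.
#' @param n_guides number of 20-nt guides to draw.
#' @param n_planted_offtargets mismatched sites planted per guide.
#' @param max_planted_mismatches maximum substitutions per planted
#'   off-target (1..20).
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return A list: `genome` (named character vector of contig sequences),
#'   `guides` (tibble `name`, `protospacer`, `pam`), `features` (tibble
#'   `contig`, `start`, `end`, `name`; 0-based half-open) and `truth`
#'   (tibble `guide`, `contig`, `start`, `end`, `strand`, `mismatches`).
#' @export
simulate_genome_and_guides <- function(n_contigs = 2, contig_length = 10000,
                                       n_guides = 3, n_planted_offtargets = 3,
                                       max_planted_mismatches = 3, seed = 1L) {
  assert_count(n_contigs, "n_contigs", 1)
  assert_count(contig_length, "contig_length", 100)
  assert_count(n_guides, "n_guides", 1)
  assert_count(n_planted_offtargets, "n_planted_offtargets", 0)
  assert_count(max_planted_mismatches, "max_planted_mismatches", 1)
  set.seed(derive_seed(seed, "genome"))

  contig_ids <- sprintf("chr%d", seq_len(n_contigs))
  genome <- setNames(vapply(contig_ids, function(i) {
    paste(sample(DNA_BASES, contig_length, replace = TRUE), collapse = "")
  }, character(1)), contig_ids)

  guides <- tibble::tibble(
    name = sprintf("g%02d", seq_len(n_guides)),
    protospacer = vapply(seq_len(n_guides), function(i) {
      paste(sample(DNA_BASES, 20, replace = TRUE), collapse = "")
    }, character(1)),
    pam = "NGG"
  )

  used <- lapply(contig_ids, function(i) integer(0))
  names(used) <- contig_ids
  truth <- list()

  plant <- function(guide_name, protospacer, mismatches) {
    site <- if (mismatches == 0) protospacer else
      mutate_protospacer(protospacer, mismatches)
    insert <- paste0(site, sample(DNA_BASES, 1), "GG")
    for (attempt in 1:200) {
      contig <- sample(contig_ids, 1)
      start0 <- sample.int(contig_length - 23L, 1) - 1L   # 0-based protospacer start
      span <- (start0 - 2L):(start0 + 25L)                # pad to keep plants apart
      if (any(span %in% used[[contig]])) next
      strand <- sample(c("+", "-"), 1)
      if (strand == "+") {
        fwd_start <- start0
        substr(genome[[contig]], start0 + 1L, start0 + 23L) <<- insert
      } else {
        # reverse-strand site: forward sequence holds revcomp(protospacer+PAM),
        # protospacer occupies forward interval [start0+3, start0+23)
        substr(genome[[contig]], start0 + 1L, start0 + 23L) <<- revcomp_chr(insert)
        fwd_start <- start0 + 3L
      }
      used[[contig]] <<- c(used[[contig]], span)
      truth[[length(truth) + 1]] <<- tibble::tibble(
        guide = guide_name, contig = contig, start = fwd_start,
        end = fwd_start + 20L, strand = strand, mismatches = mismatches
      )
      return(invisible(TRUE))
    }
    abort("could not place a site without overlap after 200 attempts")
  }

  for (i in seq_len(n_guides)) {
    plant(guides$name[i], guides$protospacer[i], 0L)
    if (n_planted_offtargets > 0) {
      for (j in seq_len(n_planted_offtargets)) {
        plant(guides$name[i], guides$protospacer[i],
              sample(max_planted_mismatches, 1))
      }
    }
  }

  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$guide, .data$contig,
                          .data$start)
  n_feat <- max(1L, nrow(truth) %/% 2L)
  feat_rows <- sort(sample(nrow(truth), n_feat))
  features <- tibble::tibble(
    contig = truth$contig[feat_rows],
    start = pmax(0L, truth$start[feat_rows] - 50L),
    end = pmin(contig_length, truth$end[feat_rows] + 50L),
    name = sprintf("regulatory_%02d", seq_len(n_feat))
  )
  list(genome = genome, guides = guides, features = features, truth = truth)
}

#' Write a simulated genome and its tracks to disk
#'
#' @param sim result of [simulate_genome_and_guides()].
#' @param dir output directory (created if needed); writes `genome.fa`
#'   (60-character lines), `features.bed` (BED3+name) and `guides.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_genome_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), fa, width = 60L)
  bed <- file.path(dir, "features.bed")
  readr::write_tsv(sim$features, bed, col_names = FALSE)
  gtsv <- file.path(dir, "guides.tsv")
  readr::write_tsv(sim$guides, gtsv)
  invisible(c(fasta = fa, bed = bed, guides = gtsv))
}
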