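# IUPAC code -> matching bases, for PAM patterns
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

validate_guide <- function(protospacer, pam) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20 || grepl("[^ACGT]", protospacer)) {
    abort("protospacer must be a 20-nt ACGT string")
  }
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), pam)) {
    abort("PAM pattern contains non-IUPAC characters")
  }
  list(protospacer = protospacer, pam = pam)
}

# mismatch counts of a 20-nt guide at every 0-based offset of one strand,
# computed as 20 vectorized base comparisons; genome ambiguity codes (N etc.)
# never match
scan_strand <- function(chars, guide_chars, pam_sets) {
  L <- length(chars)
  plen <- length(pam_sets)
  n_pos <- L - 20L - plen + 1L
  if (n_pos < 1) return(integer(0))
  mm <- integer(n_pos)
  idx <- seq_len(n_pos)
  for (k in 0:19) {
    mm <- mm + (chars[idx + k] != guide_chars[k + 1L])
  }
  pam_ok <- rep(TRUE, n_pos)
  for (k in seq_len(plen)) {
    pam_ok <- pam_ok & (chars[idx + 19L + k] %in% pam_sets[[k]])
  }
  which_hits <- which(pam_ok)
  structure(mm[which_hits], positions = which_hits - 1L)  # 0-based starts
}

#' Enumerate guide RNA off-target sites by exhaustive mismatch scan
#'
#' Scans both strands of a genome for 20-mers within `max_mismatches`
#' Hamming distance of the protospacer whose 3'-adjacent bases match the
#' PAM pattern exactly (IUPAC; PAM positions never count as mismatches).
#' Ambiguous genome bases (N) match nothing.  Reverse-strand hits report
#' the site's forward-strand 0-based half-open interval.
#'
#' @param genome named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param protospacer 20-nt ACGT guide sequence (5'->3', PAM-distal to
#'   PAM-proximal).
#' @param pam IUPAC PAM pattern 3' of the protospacer; default `"NGG"`.
#' @param max_mismatches maximum protospacer mismatches, 0..20 (default 3,
#'   the conventional bound for SpCas9 off-target surveys).
#' @param guide_name optional label carried into the result.
#' @return Tibble: `guide`, `contig`, `start`, `end` (0-based half-open,
#'   forward strand; `end - start == 20`), `strand`, `mismatches`,
#'   `site_seq` (protospacer-orientation sequence), `pam_seq`.  Sorted by
#'   (contig, start, strand).  Contigs shorter than 23 bases are skipped
#'   with a message.
#' @export
find_offtargets <- function(genome, protospacer, pam = "NGG",
                            max_mismatches = 3, guide_name = NA_character_) {
  g <- validate_guide(protospacer, pam)
  if (!is.numeric(max_mismatches) || max_mismatches < 0 || max_mismatches > 20) {
    abort("max_mismatches must be in 0..20")
  }
  genome <- load_genome(genome)
  if (length(genome) == 0) abort("empty genome")
  guide_chars <- strsplit(g$protospacer, "")[[1]]
  pam_sets <- IUPAC_SETS[strsplit(g$pam, "")[[1]]]
  site_len <- 20L + length(pam_sets)

  hits <- list()
  for (contig in names(genome)) {
    seq_f <- toupper(genome[[contig]])
    L <- nchar(seq_f)
    if (L < site_len) {
      inform(sprintf("contig %s shorter than %d bases, skipped", contig, site_len))
      next
    }
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_f else revcomp_chr(seq_f)
      chars <- strsplit(s, "")[[1]]
      mm <- scan_strand(chars, guide_chars, pam_sets)
      pos <- attr(mm, "positions")
      keep <- which(as.integer(mm) <= max_mismatches)
      if (length(keep) == 0) next
      p <- pos[keep]
      start <- if (strand == "+") p else L - (p + 20L)
      hits[[length(hits) + 1]] <- tibble::tibble(
        guide = guide_name, contig = contig,
        start = start, end = start + 20L, strand = strand,
        mismatches = as.integer(mm)[keep],
        site_seq = substring(s, p + 1L, p + 20L),
        pam_seq = substring(s, p + 21L, p + 20L + length(pam_sets))
      )
    }
  }
  out <- if (length(hits) == 0) {
    tibble::tibble(guide = character(0), contig = character(0),
                   start = integer(0), end = integer(0), strand = character(0),
                   mismatches = integer(0), site_seq = character(0),
                   pam_seq = character(0))
  } else {
    dplyr::bind_rows(hits)
  }
  dplyr::arrange(out, .data$contig, .data$start, .data$strand)
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    nm <- sub("\\s.*$", "", names(ss))
    return(setNames(as.character(ss), nm))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort("`genome` must be a named character vector, DNAStringSet, or FASTA path")
}

#' Read a BED3+name feature track
#'
#' @param path BED file: tab-separated `contig`, `start`, `end` (0-based
#'   half-open) and a `name` column, no header.
#' @return Tibble `contig`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  out <- tryCatch(
    readr::read_tsv(path, col_names = c("contig", "start", "end", "name"),
                    col_types = "ciic", progress = FALSE),
    error = function(e) abort(sprintf("malformed BED file %s: %s", path, conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed BED line %d in %s", probs$row[1], path))
  }
  if (any(is.na(out$start) | is.na(out$end))) {
    abort(sprintf("malformed BED line %d in %s",
                  which(is.na(out$start) | is.na(out$end))[1], path))
  }
  out
}

#' Annotate off-target hits with nearby regulatory features
#'
#' A hit is annotated with every feature whose interval, expanded by
#' `window_bp` on both sides, overlaps the hit's 20-bp interval by at least
#' one base.  All coordinates are 0-based half-open on the forward strand.
#'
#' @param hits tibble from [find_offtargets()].
#' @param features tibble `contig`, `start`, `end`, `name` (e.g. from
#'   [read_bed()]).
#' @param window_bp symmetric expansion of each feature in bp (default
#'   2000, a typical promoter-proximal window).
#' @return `hits` with an added `features` list-column (character vector of
#'   overlapping feature names, possibly empty) and `n_features`; row
#'   order preserved.
#' @export
annotate_hits <- function(hits, features, window_bp = 2000) {
  assert_number(window_bp, "window_bp", 0)
  ann <- lapply(seq_len(nrow(hits)), function(i) {
    same <- features$contig == hits$contig[i]
    ov <- same &
      hits$start[i] < features$end + window_bp &
      features$start - window_bp < hits$end[i]
    features$name[ov]
  })
  hits$features <- ann
  hits$n_features <- lengths(ann)
  hits
}
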