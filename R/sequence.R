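#' @useDynLib fgcohesion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate sd median quantile setNames aggregate coef lm
#' @importFrom utils write.csv read.csv head tail
"_PACKAGE"

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct an FG-domain sequence object
#'
#' Represents a (sub)sequence of an intrinsically disordered FG-repeat domain
#' as an ordered vector of one-letter amino-acid codes with 1-based UniProt
#' style numbering. `numbering_offset` gives the residue number of the first
#' position, so sub-domains extracted from a longer protein keep their
#' original numbering.
#'
#' @param residues character vector of one-letter codes, or a single string.
#' @param id text label for the sequence.
#' @param numbering_offset 1-based residue number of the first position.
#' @return An object of class `fg_sequence` with elements `id`, `residues`
#'   and `numbering_offset`.
#' @examples
#' fg_sequence("GLFGAAFGA", id = "toy")
#' @export
fg_sequence <- function(residues, id = "seq", numbering_offset = 1L) {
  if (is.character(residues) && length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  bad <- setdiff(unique(residues), AA1)
  if (length(bad) > 0L)
    stop("non-standard amino-acid code(s): ", paste(bad, collapse = ", "))
  if (length(residues) < 2L)
    stop("sequence must have at least 2 residues")
  numbering_offset <- as.integer(numbering_offset)
  structure(
    list(id = as.character(id), residues = residues,
         numbering_offset = numbering_offset),
    class = "fg_sequence")
}

#' @export
print.fg_sequence <- function(x, ...) {
  cat(sprintf("<fg_sequence> %s: %d residues (numbered %d-%d)\n",
              x$id, length(x$residues), x$numbering_offset,
              x$numbering_offset + length(x$residues) - 1L))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.fg_sequence <- function(x) length(x$residues)

#' @export
as.character.fg_sequence <- function(x, ...) paste(x$residues, collapse = "")

## residue at 1-based *numbered* position (respects numbering_offset)
seq_residue_at <- function(seq, position) {
  i <- position - seq$numbering_offset + 1L
  if (i < 1L || i > length(seq$residues))
    stop(sprintf("position %d outside sequence numbering [%d, %d]",
                 position, seq$numbering_offset,
                 seq$numbering_offset + length(seq$residues) - 1L))
  seq$residues[i]
}

#' Locate FG and GLFG motifs and their phenylalanine sites
#'
#' Scans the sequence for GLFG (Gly-Leu-Phe-Gly) and FG (Phe-Gly) motifs.
#' GLFG takes precedence: an FG dipeptide whose phenylalanine is already the
#' phenylalanine of a GLFG occurrence is not reported a second time, so every
#' phenylalanine site appears at most once. Results are sorted by the
#' phenylalanine residue number.
#'
#' @param seq an [fg_sequence()].
#' @return A data.frame with columns `kind` ("FG" or "GLFG"), `start`
#'   (1-based residue number where the motif begins) and `phe_index`
#'   (residue number of the motif's phenylalanine).
#' @examples
#' scan_motifs(fg_sequence("GLFGAAFGA"))
#' @export
scan_motifs <- function(seq) {
  stopifnot(inherits(seq, "fg_sequence"))
  r <- seq$residues
  n <- length(r)
  off <- seq$numbering_offset
  glfg_start <- which(r[seq_len(max(0L, n - 3L))] == "G" &
                      r[seq_len(max(0L, n - 3L)) + 1L] == "L" &
                      r[seq_len(max(0L, n - 3L)) + 2L] == "F" &
                      r[seq_len(max(0L, n - 3L)) + 3L] == "G")
  glfg_phe <- glfg_start + 2L
  fg_start <- which(r[seq_len(max(0L, n - 1L))] == "F" &
                    r[seq_len(max(0L, n - 1L)) + 1L] == "G")
  fg_phe <- setdiff(fg_start, glfg_phe)  # GLFG precedence on the F site
  out <- data.frame(
    kind = c(rep("GLFG", length(glfg_phe)), rep("FG", length(fg_phe))),
    start = c(glfg_start, fg_phe) + off - 1L,
    phe_index = c(glfg_phe, fg_phe) + off - 1L,
    stringsAsFactors = FALSE)
  out <- out[order(out$phe_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phenylalanine sites of all FG-family motifs
#'
#' Residue numbers of the phenylalanines belonging to FG or GLFG motifs
#' (see [scan_motifs()]); these are the sites whose pairwise distances
#' measure intramolecular cohesion of the domain. By default both FG and
#' GLFG phenylalanines are included.
#'
#' @param seq an [fg_sequence()].
#' @param include_glfg include phenylalanines of GLFG motifs (default TRUE).
#' @return Strictly increasing integer vector of residue numbers (possibly
#'   empty).
#' @examples
#' phenylalanine_sites(fg_sequence("GLFGAAFGA"))  # 3, 7
#' @export
phenylalanine_sites <- function(seq, include_glfg = TRUE) {
  m <- scan_motifs(seq)
  if (!include_glfg) m <- m[m$kind == "FG", , drop = FALSE]
  as.integer(m$phe_index)
}

#' Specify a single amino-acid substitution
#'
#' @param ref_aa one-letter code of the reference residue.
#' @param position 1-based residue number.
#' @param alt_aa one-letter code of the replacement residue.
#' @return An object of class `variant_spec`.
#' @examples
#' variant_spec("G", 28, "D")  # the NUP98 p.G28D substitution
#' @export
variant_spec <- function(ref_aa, position, alt_aa) {
  ref_aa <- toupper(ref_aa); alt_aa <- toupper(alt_aa)
  stopifnot(ref_aa %in% AA1, alt_aa %in% AA1)
  if (ref_aa == alt_aa) stop("ref_aa and alt_aa must differ")
  structure(list(ref_aa = ref_aa, position = as.integer(position),
                 alt_aa = alt_aa), class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> p.%s%d%s\n", x$ref_aa, x$position, x$alt_aa))
  invisible(x)
}

#' Apply a point variant to a sequence
#'
#' Returns a copy of the sequence with the substitution applied. The
#' reference residue is checked against the sequence at the variant position
#' (in the sequence's own numbering); a mismatch signals a wrong numbering
#' convention and is an error.
#'
#' @param seq an [fg_sequence()].
#' @param v a [variant_spec()].
#' @return A new `fg_sequence` differing from `seq` at exactly `v$position`.
#' @examples
#' wt <- fg_sequence(strrep("AG", 20), id = "wt")
#' mut <- apply_variant(wt, variant_spec("G", 28, "D"))
#' @export
apply_variant <- function(seq, v) {
  stopifnot(inherits(seq, "fg_sequence"), inherits(v, "variant_spec"))
  found <- seq_residue_at(seq, v$position)
  if (found != v$ref_aa)
    stop(sprintf(
      "reference mismatch at position %d: expected %s, found %s",
      v$position, v$ref_aa, found))
  out <- seq
  out$residues[v$position - seq$numbering_offset + 1L] <- v$alt_aa
  out$id <- sprintf("%s_%s%d%s", seq$id, v$ref_aa, v$position, v$alt_aa)
  out
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (single or multiple records).
#' @return A list of [fg_sequence()] objects, one per record.
#' @export
read_fg_fasta <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  ali <- fa$ali
  lapply(seq_len(nrow(ali)), function(i) {
    res <- ali[i, ]
    res <- res[!(res %in% c("-", ".", " ")) & !is.na(res)]
    fg_sequence(res, id = rownames(ali)[i])
  })
}

#' Write sequences to a FASTA file
#'
#' Records are wrapped at 60 columns.
#'
#' @param seqs an [fg_sequence()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fg_fasta <- function(seqs, path) {
  if (inherits(seqs, "fg_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    txt <- paste(s$residues, collapse = "")
    starts <- seq(1L, nchar(txt), by = 60L)
    writeLines(substring(txt, starts, pmin(starts + 59L, nchar(txt))), con)
  }
  invisible(path)
}

#' Write a motif table to CSV
#'
#' Columns `kind,start,phe_index` as produced by [scan_motifs()].
#'
#' @param motifs data.frame from [scan_motifs()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_motif_csv <- function(motifs, path) {
  utils::write.csv(motifs[, c("kind", "start", "phe_index")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate an FG-repeat-like synthetic sequence
#'
#' Builds a disordered-domain-like sequence by alternating FG-family motifs
#' (FG or GLFG) with hydrophilic linkers drawn from a composition typical of
#' nucleoporin FG domains (rich in G, S, T, N, Q, A). Used in tests and as
#' the synthetic stand-in for a real FG domain when no FASTA input is given.
#'
#' @param n_res total length of the sequence.
#' @param motif_period approximate spacing between consecutive motifs.
#' @param glfg_fraction fraction of motifs emitted as GLFG rather than FG.
#' @param seed integer RNG seed.
#' @param id sequence label.
#' @return An [fg_sequence()] of length `n_res`.
#' @export
random_fg_sequence <- function(n_res, motif_period = 12L,
                               glfg_fraction = 0.3, seed = 1L,
                               id = "synthetic_fg") {
  stopifnot(n_res >= 6, motif_period >= 5)
  linker_pool <- c("G", "S", "T", "N", "Q", "A")
  linker_w <- c(0.28, 0.22, 0.16, 0.14, 0.12, 0.08)
  res <- withr_seed(seed, {
    out <- character(0)
    while (length(out) < n_res) {
      k <- max(1L, motif_period - 4L +
                 sample.int(5L, 1L) - 3L)  # jittered linker length
      out <- c(out, sample(linker_pool, k, replace = TRUE, prob = linker_w))
      motif <- if (stats::runif(1) < glfg_fraction) c("G", "L", "F", "G")
               else c("F", "G")
      out <- c(out, motif)
    }
    out[seq_len(n_res)]
  })
  fg_sequence(res, id = id)
}

## evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
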