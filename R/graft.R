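## Motif grafting: thread a sensing-domain prefix into every start offset of
## an alpha-helical latch segment. The heptad class (offset mod 7) labels the
## approximate helical face of each placement; enumeration itself steps by
## single residues.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_aa <- function(seq, what) {
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(ch), .AA20)
  if (length(bad)) {
    stop(what, " contains non-standard residues: ", paste(bad, collapse = ", "))
  }
  paste(ch, collapse = "")
}

#' Latch segment available for motif grafting
#'
#' @param sequence Amino-acid sequence of the graftable latch span
#'   (standard 20-letter alphabet).
#' @param start_residue 1-based residue number of the first latch position
#'   in the full cage protein (e.g. 610).
#' @return An object of class `latch_segment` with derived `end_residue`.
#' @examples
#' latch_segment(paste(rep("A", 35), collapse = ""), start_residue = 610)
#' @export
latch_segment <- function(sequence, start_residue = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L,
            is.numeric(start_residue), start_residue >= 1)
  sequence <- .check_aa(sequence, "latch")
  structure(list(sequence = sequence,
                 start_residue = as.integer(start_residue),
                 end_residue = as.integer(start_residue) + nchar(sequence) - 1L),
            class = "latch_segment")
}

#' Sensing motif with allowed prefix lengths
#'
#' @param sequence Amino-acid sequence of the binding motif.
#' @param min_len,max_len Allowed prefix lengths to graft (defaults 7 and 11).
#' @return An object of class `binding_motif`.
#' @export
binding_motif <- function(sequence, min_len = 7L, max_len = 11L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            min_len >= 1L, min_len <= max_len, max_len <= nchar(sequence))
  sequence <- .check_aa(sequence, "motif")
  structure(list(sequence = sequence, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "binding_motif")
}

#' Substitute a motif into a latch at a given offset
#'
#' Pure substring replacement: the motif occupies
#' `[start_offset, start_offset + nchar(motif_prefix))` (0-based) and all
#' flanking latch residues are preserved verbatim.
#'
#' @param latch A [latch_segment()].
#' @param motif_prefix Character string to thread.
#' @param start_offset 0-based offset within the latch.
#' @return Threaded sequence (same length as the latch).
#' @export
thread_motif <- function(latch, motif_prefix, start_offset) {
  stopifnot(inherits(latch, "latch_segment"), is.character(motif_prefix))
  L <- nchar(motif_prefix)
  span <- nchar(latch$sequence)
  if (start_offset < 0 || start_offset + L > span) {
    stop(sprintf("offset %d with motif length %d does not fit in latch span %d",
                 start_offset, L, span))
  }
  paste0(substr(latch$sequence, 1L, start_offset),
         motif_prefix,
         substr(latch$sequence, start_offset + L + 1L, span))
}

#' Heptad register class of a start offset
#'
#' Labels the approximate alpha-helical face of a placement as
#' `offset mod 7` (heptad approximation of the 3.6-residue-per-turn helix).
#' A labeling convenience only; it never filters placements.
#'
#' @param start_offset 0-based start offset (vectorized).
#' @return Integer in 0..6.
#' @export
register_class <- function(start_offset) {
  stopifnot(is.numeric(start_offset), all(start_offset >= 0))
  as.integer(start_offset) %% 7L
}

#' Enumerate all motif placements in a latch segment
#'
#' One candidate per (prefix length `L` in `[min_len, max_len]`, start
#' offset `p` in `[0, span - L]`), ordered by `L` ascending then `p`
#' ascending, giving `sum_L (span - L + 1)` candidates.
#'
#' @param latch A [latch_segment()].
#' @param motif A [binding_motif()].
#' @return A `graft_candidates` data frame with columns `id`, `motif_len`,
#'   `start_offset` (0-based), `start_residue`/`end_residue` (1-based in
#'   cage coordinates), `register_class` and `threaded_sequence`. Returns an
#'   empty set with a warning if no prefix length fits.
#' @examples
#' lat <- latch_segment(paste(rep("A", 35), collapse = ""), 610)
#' mot <- binding_motif("TSNTIRVFLPNKQRT", 7, 11)
#' nrow(enumerate_placements(lat, mot)) # 135
#' @export
enumerate_placements <- function(latch, motif) {
  stopifnot(inherits(latch, "latch_segment"), inherits(motif, "binding_motif"))
  span <- nchar(latch$sequence)
  lens <- seq.int(motif$min_len, motif$max_len)
  lens <- lens[lens <= span]
  rows <- list()
  for (L in lens) {
    prefix <- substr(motif$sequence, 1L, L)
    for (p in 0:(span - L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        motif_len = L, start_offset = p,
        start_residue = latch$start_residue + p,
        end_residue = latch$start_residue + p + L - 1L,
        register_class = register_class(p),
        threaded_sequence = thread_motif(latch, prefix, p),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning("motif minimum length exceeds latch span; no candidates")
    out <- data.frame(motif_len = integer(), start_offset = integer(),
                      start_residue = integer(), end_residue = integer(),
                      register_class = integer(),
                      threaded_sequence = character())
  } else {
    out <- do.call(rbind, rows)
  }
  out <- cbind(id = sprintf("graft_L%02d_off%02d", out$motif_len, out$start_offset),
               out)
  out$id <- as.character(out$id)
  structure(out, class = c("graft_candidates", "data.frame"),
            latch = latch, motif = motif)
}

#' Write graft candidates to FASTA
#'
#' Headers encode residue coordinates, offset, motif length, and register
#' class as `id res<start>-<end> off=<p> L=<len> reg=<class>`, and round-trip
#' through [read_candidates_fasta()].
#'
#' @param candidates A non-empty `graft_candidates` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_candidates_fasta <- function(candidates, path) {
  stopifnot(inherits(candidates, "graft_candidates"))
  if (nrow(candidates) == 0L) stop("no candidates to write")
  seqs <- Biostrings::AAStringSet(candidates$threaded_sequence)
  names(seqs) <- sprintf("%s res%d-%d off=%d L=%d reg=%d",
                         candidates$id, candidates$start_residue,
                         candidates$end_residue, candidates$start_offset,
                         candidates$motif_len, candidates$register_class)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read graft candidates back from FASTA
#'
#' @param path FASTA written by [write_candidates_fasta()].
#' @return Data frame with `id`, `start_offset`, `motif_len`,
#'   `register_class`, `start_residue`, `end_residue`, `threaded_sequence`.
#' @export
read_candidates_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  grab <- function(pat) as.integer(sub(paste0(".*", pat, "=(\\d+).*"), "\\1", hdr))
  res <- regmatches(hdr, regexec("res(\\d+)-(\\d+)", hdr))
  data.frame(
    id = sub(" .*", "", hdr),
    start_residue = vapply(res, function(m) as.integer(m[2]), integer(1)),
    end_residue = vapply(res, function(m) as.integer(m[3]), integer(1)),
    start_offset = grab("off"),
    motif_len = grab("L"),
    register_class = grab("reg"),
    threaded_sequence = as.character(seqs),
    stringsAsFactors = FALSE, row.names = NULL)
}
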