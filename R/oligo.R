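#' Oligonucleotide sequence with an alphabet role
#'
#' Lightweight container for a morpholino (MO), RNA, or DNA sequence. MOs and
#' DNA use the alphabet \{A,C,G,T\}; RNA uses \{A,C,G,U\}. Morpholino bases are
#' standard nucleobases on a morpholine backbone, so their base-pairing
#' alphabet is that of DNA.
#'
#' @param residues character scalar, the sequence 5'->3' (case-insensitive).
#' @param role one of `"MO"`, `"RNA"`, `"DNA"`.
#' @param name optional identifier.
#' @return An object of class `oligo` with fields `name`, `residues`
#'   (character vector of single bases), `role`, and `length`.
#' @examples
#' mo <- oligo("CCTCTTACCTCAGTTACAATTTATA", role = "MO", name = "cMO")
#' gc_content(mo)
#' @export
oligo <- function(residues, role = c("MO", "RNA", "DNA"), name = NULL) {
  role <- match.arg(role)
  if (length(residues) == 1L && is.character(residues)) {
    residues <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  } else {
    residues <- toupper(as.character(residues))
  }
  if (length(residues) == 0L) stop("empty sequence")
  alpha <- oligo_alphabet(role)
  bad <- which(!(residues %in% alpha))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d for role %s",
                 residues[bad[1L]], bad[1L], role))
  }
  structure(
    list(name = if (is.null(name)) "" else as.character(name),
         residues = residues, role = role, length = length(residues)),
    class = "oligo")
}

oligo_alphabet <- function(role) {
  switch(role, MO = c("A", "C", "G", "T"), DNA = c("A", "C", "G", "T"),
         RNA = c("A", "C", "G", "U"))
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo %s> %s [%s, %d nt, GC %.0f%%]\n",
              x$role, paste(x$residues, collapse = ""),
              if (nzchar(x$name)) x$name else "unnamed",
              x$length, gc_content(x)))
  invisible(x)
}

#' @export
as.character.oligo <- function(x, ...) paste(x$residues, collapse = "")

#' @export
length.oligo <- function(x) x$length

as_oligo <- function(x, role, name = NULL) {
  if (inherits(x, "oligo")) x else oligo(x, role = role, name = name)
}

#' GC content of a sequence, in percent
#'
#' @param seq an [oligo], or a character scalar (interpreted as DNA/MO unless
#'   it contains U).
#' @return Numeric scalar in \[0, 100\]: `100 * (#G + #C) / length`. The raw
#'   value is returned; round to the nearest integer for display.
#' @examples
#' gc_content("CCTCTTACCTCAGTTACAATTTATA")  # 32
#' @export
gc_content <- function(seq) {
  if (!inherits(seq, "oligo")) {
    role <- if (grepl("U", toupper(paste(seq, collapse = "")))) "RNA" else "DNA"
    seq <- as_oligo(seq, role)
  }
  100 * sum(seq$residues %in% c("G", "C")) / seq$length
}

#' Reverse complement of a sequence
#'
#' Antiparallel complement: A<->T (DNA output) or A<->U (RNA output), G<->C.
#' An RNA input's U complements to A in either output alphabet.
#'
#' @param seq an [oligo] or character scalar.
#' @param output_role `"DNA"` or `"RNA"` alphabet for the result.
#' @return An [oligo] of the requested role, same length.
#' @export
reverse_complement <- function(seq, output_role = c("DNA", "RNA")) {
  output_role <- match.arg(output_role)
  if (!inherits(seq, "oligo")) {
    role <- if (grepl("U", toupper(paste(seq, collapse = "")))) "RNA" else "DNA"
    seq <- as_oligo(seq, role)
  }
  comp <- c(A = if (output_role == "DNA") "T" else "U",
            T = "A", U = "A", G = "C", C = "G")
  oligo(rev(unname(comp[seq$residues])), role = output_role,
        name = if (nzchar(seq$name)) paste0(seq$name, "_rc") else NULL)
}

#' The five morpholino sequences used in the Brachyury knockdown study
#'
#' Returns the two splice-blocking and two translation-blocking MOs against
#' the Brachyury paralogs t and t2, plus the standard control MO (cMO),
#' as a named list of [oligo] objects (role `"MO"`). Their GC contents span
#' 32--65%, the range over which innate-immune induction was observed to vary.
#'
#' @return Named list of `oligo` objects: `t_splice`, `t_transl`, `t2_splice`,
#'   `t2_transl`, `cMO`.
#' @export
study_morpholinos <- function() {
  seqs <- c(t_splice  = "TGGAGAGACCCTGATCTTACCTTCC",
            t_transl  = "GGCTTCCAAGCGCACACACTGGG",
            t2_splice = "GAAAGGTCCATATTCTCTTACCTTC",
            t2_transl = "AGCTGTGCCTGTGCTCATTGTATTG",
            cMO       = "CCTCTTACCTCAGTTACAATTTATA")
  mapply(oligo, seqs, name = names(seqs),
         MoreArgs = list(role = "MO"), SIMPLIFY = FALSE)
}

#' RNA oligonucleotides used in the biolayer-interferometry binding assays
#'
#' The biotin-tagged RNA probes: the canonical t target site, the dtymk
#' off-target site, its G-to-C point mutant (removing a wobble pair), and a
#' scrambled control. The 5' poly(A) stretch is the linker between the biotin
#' tag and the binding site and is kept, since the scan treats it like any
#' other residue.
#'
#' @return Named list of `oligo` objects (role `"RNA"`): `t_target`,
#'   `dtymk_offtarget`, `dtymk_GtoC`, `scrambled`.
#' @export
study_rna_oligos <- function() {
  seqs <- c(t_target        = "AAAAAAAAGGAAGGUAAGAUCAGGGUCUCUCCA",
            dtymk_offtarget = "AAAAAAAAGGAGGUAAGAGAUCAUUUGUAGGAU",
            dtymk_GtoC      = "AAAAAAAAGCAGGUAAGAGAUCAUUUGUAGGAU",
            scrambled       = "AAAAAAAAAGUUAUGGCGAGAGUGGAUAUUAGA")
  mapply(oligo, seqs, name = names(seqs),
         MoreArgs = list(role = "RNA"), SIMPLIFY = FALSE)
}

#' Read sequences for scanning
#'
#' Reads either a FASTA file (via Biostrings) or a two-column
#' `name<TAB>sequence` text file into a named list of [oligo] objects.
#'
#' @param path file path.
#' @param role alphabet role to assign (`"MO"`, `"RNA"`, `"DNA"`).
#' @param format `"auto"` (FASTA if the first non-blank character is `>`),
#'   `"fasta"`, or `"tsv"`.
#' @return Named list of `oligo` objects.
#' @export
read_sequences <- function(path, role = c("DNA", "RNA", "MO"),
                           format = c("auto", "fasta", "tsv")) {
  role <- match.arg(role)
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(trimws(first), ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- if (role == "RNA") Biostrings::readRNAStringSet(path)
          else Biostrings::readDNAStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("name", "sequence"),
                             colClasses = "character")
    seqs <- stats::setNames(tab$sequence, tab$name)
  }
  mapply(oligo, seqs, name = names(seqs),
         MoreArgs = list(role = role), SIMPLIFY = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs named list of [oligo] objects or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  chr <- vapply(seqs, function(s) if (inherits(s, "oligo")) as.character(s) else s, "")
  is_rna <- any(grepl("U", chr, fixed = TRUE))
  ss <- if (is_rna) Biostrings::RNAStringSet(chr) else Biostrings::DNAStringSet(chr)
  names(ss) <- names(chr)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
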