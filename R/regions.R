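#' Region definitions for the IRE1-alpha ER-lumenal domain
#'
#' A `region` records a named segment of the lumenal domain (LD) in LD
#' residue numbering (1-based, inclusive) together with its one-letter
#' amino-acid sequence, when known. Sequences are validated against the 20
#' canonical residues and against the coordinate span.
#'
#' @param name short label, e.g. `"DR2"`.
#' @param start,end first and last LD residue of the segment (inclusive).
#' @param sequence one-letter amino-acid string, or `NA` for boundary-only
#'   entries whose sequence is not built in.
#' @return An object of class `region`.
#' @export
region <- function(name, start, end, sequence = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("region '", name, "': need 1 <= start <= end, got [", start, ", ", end, "]")
  if (!is.na(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != end - start + 1L)
      stop("region '", name, "': sequence length ", nchar(sequence),
           " does not match span ", end - start + 1L)
    bad <- setdiff(strsplit(sequence, "")[[1]], AMINO_ACIDS)
    if (length(bad))
      stop("region '", name, "': non-canonical residues: ",
           paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, start = start, end = end, sequence = sequence),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s  LD %d-%d  (%d aa)%s\n", x$name, x$start, x$end,
              x$end - x$start + 1L,
              if (is.na(x$sequence)) "  [boundaries only]" else ""))
  if (!is.na(x$sequence)) cat("  ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' @export
length.region <- function(x) x$end - x$start + 1L

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Sequences of the isolated disordered-region peptides as simulated, in LD
# numbering. The "linker" entry holds the full 369-443 peptide; DR3 and the
# membrane-proximal linker proper are coordinate slices of it.
DR1_SEQ    <- "LTGEKQQTLSSAFADSLSPSTS"
DR2_SEQ    <- "VPRGSTLPLLEGPQTDGVTIGDKGESVITPSTDVKFDPGLKSKNKLNYLRNY"
LINKER_SEQ <- "LSASTKMLERFPNNLPKHRENVIPADSEKKSFEEVINLVDQTSENAPTTVSRDVEEKPAHAPARPEAPVDSMLKD"

#' Built-in lumenal-domain regions
#'
#' Returns the disordered regions of the human IRE1-alpha lumenal domain with
#' their LD-coordinate boundaries: DR1 (131-152), DR2 (307-358) and the
#' linker-region peptide (369-443) with built-in sequences, plus boundary-only
#' entries for DR3 (369-389), the linker proper (390-443), the core lumenal
#' domain cLD (24-389) and the full LD (24-443). DR3 and the linker proper are
#' slices of the 369-443 peptide and carry the corresponding subsequences.
#'
#' @return Named list of [region] objects.
#' @examples
#' builtin_regions()$DR2
#' @export
builtin_regions <- function() {
  slice <- function(from, to)
    substr(LINKER_SEQ, from - 369L + 1L, to - 369L + 1L)
  list(
    DR1         = region("DR1", 131L, 152L, DR1_SEQ),
    DR2         = region("DR2", 307L, 358L, DR2_SEQ),
    linker      = region("linker", 369L, 443L, LINKER_SEQ),
    DR3         = region("DR3", 369L, 389L, slice(369L, 389L)),
    linker_only = region("linker_only", 390L, 443L, slice(390L, 443L)),
    cLD         = region("cLD", 24L, 389L),
    LD          = region("LD", 24L, 443L)
  )
}

#' Map an LD residue number into a region
#'
#' Converts LD numbering to the chain-internal (1-based) index used by
#' simulated peptides of that region, returning the index and the residue.
#'
#' @param region a [region] with a sequence.
#' @param ld_residue LD residue number, within `[region$start, region$end]`.
#' @return List with `index` (chain-internal, 1-based) and `residue`
#'   (one-letter code).
#' @examples
#' map_position(builtin_regions()$DR2, 328)  # Asp328 -> index 22, "D"
#' @export
map_position <- function(region, ld_residue) {
  stopifnot(inherits(region, "region"))
  ld_residue <- as.integer(ld_residue)
  if (ld_residue < region$start || ld_residue > region$end)
    stop("LD residue ", ld_residue, " outside region '", region$name,
         "' bounds [", region$start, ", ", region$end, "]")
  idx <- ld_residue - region$start + 1L
  res <- if (is.na(region$sequence)) NA_character_ else
    substr(region$sequence, idx, idx)
  list(index = idx, residue = res)
}

#' Inverse of [map_position()]: chain-internal index to LD residue number
#' @param region a [region].
#' @param index chain-internal 1-based index.
#' @return LD residue number.
#' @export
unmap_position <- function(region, index) {
  index <- as.integer(index)
  n <- region$end - region$start + 1L
  if (index < 1L || index > n)
    stop("index ", index, " outside 1..", n, " for region '", region$name, "'")
  region$start + index - 1L
}

#' Residue classification scheme
#'
#' Maps every canonical residue to exactly one class. The default classes
#' reflect the interaction chemistry relevant for disordered-region
#' clustering: negatively charged (D, E), positively charged (K, R), aromatic
#' (F, Y, W), hydrophobic (A, I, L, M, V, C), polar (N, Q, S, T, G, H) and
#' other (P).
#'
#' @return Named character vector, names are one-letter codes.
#' @export
residue_classes <- function() {
  c(D = "negative", E = "negative",
    K = "positive", R = "positive",
    F = "aromatic", Y = "aromatic", W = "aromatic",
    A = "hydrophobic", I = "hydrophobic", L = "hydrophobic",
    M = "hydrophobic", V = "hydrophobic", C = "hydrophobic",
    N = "polar", Q = "polar", S = "polar", T = "polar", G = "polar",
    H = "polar",
    P = "other")
}

#' Residue-class composition of a region
#'
#' @param region a [region] with a sequence (boundary-only regions error).
#' @param scheme named class vector as from [residue_classes()].
#' @return List with `counts` and `fractions` per class (all classes of the
#'   scheme present), plus `n`. For an empty sequence all counts are 0 and
#'   `fractions` is `NA` with `undefined = TRUE`.
#' @export
composition <- function(region, scheme = residue_classes()) {
  stopifnot(inherits(region, "region"))
  if (is.na(region$sequence))
    stop("region '", region$name, "' has no sequence")
  classes <- sort(unique(scheme))
  aa <- strsplit(region$sequence, "")[[1]]
  counts <- table(factor(scheme[aa], levels = classes))
  counts <- stats::setNames(as.integer(counts), classes)
  n <- length(aa)
  if (n == 0L)
    return(list(counts = counts, fractions = stats::setNames(rep(NA_real_,
      length(classes)), classes), n = 0L, undefined = TRUE))
  list(counts = counts, fractions = counts / n, n = n, undefined = FALSE)
}

#' Read / write peptides as FASTA
#'
#' Thin wrappers over Biostrings for arbitrary peptide sets; built-in regions
#' can be exported with [regions_to_fasta()].
#'
#' @param path file path.
#' @return `read_peptides_fasta`: named character vector of sequences.
#' @export
read_peptides_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), names(aas))
}

#' @rdname read_peptides_fasta
#' @param sequences named character vector of peptide sequences.
#' @export
write_peptides_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' @rdname read_peptides_fasta
#' @param regions list of [region] objects; entries without sequences are
#'   dropped.
#' @export
regions_to_fasta <- function(regions, path) {
  regions <- Filter(function(r) !is.na(r$sequence), regions)
  seqs <- vapply(regions, `[[`, "", "sequence")
  names(seqs) <- vapply(regions, function(r)
    sprintf("%s LD:%d-%d", r$name, r$start, r$end), "")
  write_peptides_fasta(seqs, path)
}
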