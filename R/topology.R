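#' Coarse-grained chain topology for a peptide species
#'
#' Builds the bead-level description of one chain species from its sequence:
#' one backbone bead per residue (default), or two beads per residue
#' (backbone + sidechain) to exercise the bead-to-residue aggregation rule.
#' Beads carry a residue class, an integer charge (+1 for K/R, -1 for D/E,
#' otherwise 0) and a sticker flag. Sticker beads are those whose residue
#' class is in `sticker_classes`; only sticker beads feel the attractive
#' wells during simulation. With two beads per residue the sidechain bead
#' carries the class/charge/sticker annotation and the backbone bead is inert.
#'
#' @param name species label, e.g. `"DR2"`.
#' @param sequence one-letter amino-acid string.
#' @param beads_per_residue 1 or 2.
#' @param sticker_classes residue classes whose beads are stickers; default
#'   the charged and aromatic classes that dominate the inter-chain contacts
#'   of clustering disordered regions.
#' @param scheme residue classification, see [residue_classes()].
#' @return Object of class `chain_topology` with elements `name`, `sequence`,
#'   `beads_per_residue`, and a per-bead data frame `beads` (columns
#'   `residue`, `slot`, `aa`, `class`, `charge`, `sticker`, `type`), plus a
#'   `bonds` matrix (bead index pairs).
#' @examples
#' top <- chain_topology("DR1", "LTGEKQQTLSSAFADSLSPSTS")
#' sum(top$beads$sticker)
#' @export
chain_topology <- function(name, sequence,
                           beads_per_residue = 1L,
                           sticker_classes = c("negative", "positive", "aromatic"),
                           scheme = residue_classes()) {
  stopifnot(beads_per_residue %in% c(1L, 2L))
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, AMINO_ACIDS)
  if (length(bad)) stop("non-canonical residues: ", paste(unique(bad), collapse = ", "))
  n <- length(aa)
  if (n < 1L) stop("empty sequence")
  cls <- unname(scheme[aa])
  chg <- ifelse(cls == "positive", 1L, ifelse(cls == "negative", -1L, 0L))
  stk <- cls %in% sticker_classes

  if (beads_per_residue == 1L) {
    beads <- data.frame(
      residue = seq_len(n), slot = 1L, aa = aa, class = cls,
      charge = chg, sticker = stk, type = "BB",
      stringsAsFactors = FALSE)
    bonds <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else
      matrix(integer(), 0L, 2L)
  } else {
    # backbone bead (odd index) inert, sidechain bead (even index) annotated
    beads <- data.frame(
      residue = rep(seq_len(n), each = 2L),
      slot = rep(c(1L, 2L), n),
      aa = rep(aa, each = 2L),
      class = rep(cls, each = 2L),
      charge = as.integer(rep(chg, each = 2L) * rep(c(0L, 1L), n)),
      sticker = rep(stk, each = 2L) & rep(c(FALSE, TRUE), n),
      type = rep(c("BB", "SC"), n),
      stringsAsFactors = FALSE)
    bb <- seq(1L, 2L * n, by = 2L)
    bonds <- rbind(
      if (n > 1L) cbind(bb[-n], bb[-1L]) else matrix(integer(), 0L, 2L),
      cbind(bb, bb + 1L))
  }
  structure(list(name = name, sequence = sequence,
                 beads_per_residue = as.integer(beads_per_residue),
                 beads = beads, bonds = bonds),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology> %s: %d residues, %d beads (%d/residue), %d stickers\n",
              x$name, nchar(x$sequence), nrow(x$beads), x$beads_per_residue,
              sum(x$beads$sticker)))
  invisible(x)
}

#' Number of beads in a chain of this topology
#' @param topology a [chain_topology()].
#' @return integer bead count.
#' @export
n_beads <- function(topology) nrow(topology$beads)

#' Chain topology for a built-in region
#'
#' Convenience wrapper: `region_topology("DR2")` is
#' `chain_topology("DR2", builtin_regions()$DR2$sequence, ...)`.
#'
#' @param name name of a built-in region with a sequence.
#' @param ... passed to [chain_topology()].
#' @export
region_topology <- function(name, ...) {
  regs <- builtin_regions()
  if (!name %in% names(regs)) stop("unknown built-in region: ", name)
  r <- regs[[name]]
  if (is.na(r$sequence)) stop("region '", name, "' has no built-in sequence")
  chain_topology(name, r$sequence, ...)
}
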