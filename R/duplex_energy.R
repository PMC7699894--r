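# Nearest-neighbor duplex free energy. The model is deliberately compact:
# a duplex-initiation penalty, the 16 Watson-Crick dinucleotide stacking
# terms (Xia et al. 37 degC values, kcal/mol), a single stacking constant for
# stacks that involve a G:U wobble, and one fixed penalty per interior
# loop/bulge event. Only relative wildtype-vs-mutant stability matters
# downstream, so terminal-pair corrections and full loop tables are omitted.

# 5'-t1 t2-3' (target) over 3'-m1 m2-5' (miRNA), keyed "t1t2/m1m2". For a
# Watson-Crick stack the bottom strand is the complement of the top, so the
# 10 unique parameters (plus 6 symmetry partners, dG(5'XY/3'X'Y') ==
# dG(5'Y'X'/3'YX)) expand over the 16 top-strand dinucleotides.
wc_stack_table <- function() {
  top <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
           CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
           GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
           CG = -2.36, GC = -3.42, GG = -3.26, CC = -3.26)
  setNames(unname(top),
           paste0(names(top), "/", wc_complement_rna(names(top))))
}

#' Nearest-neighbor energy parameters
#'
#' @param initiation duplex initiation penalty in kcal/mol (> 0). The
#'   default, 0.5, is intentionally small: the pipeline only compares
#'   wildtype against mutant duplexes, where the initiation term cancels,
#'   and a small value keeps even a minimal two-pair helix at or below
#'   0 kcal/mol. Set it to a Turner-scale value (about 4.1) for
#'   literature-comparable absolute energies.
#' @param gu_stack stacking term (kcal/mol, < 0) used for any dinucleotide
#'   stack involving a G:U wobble (default -1.3, a single representative
#'   value in place of the full wobble table).
#' @param loop_penalty penalty in kcal/mol per interior loop or bulge event
#'   (default 3.5).
#' @return list of class `nn_params` with the 16 Watson-Crick stack terms in
#'   `$stack`.
#' @export
nn_params <- function(initiation = 0.5, gu_stack = -1.3, loop_penalty = 3.5) {
  stopifnot(initiation > 0, gu_stack < 0, loop_penalty >= 0)
  stack <- wc_stack_table()
  stopifnot(all(stack < 0))
  structure(list(stack = stack, initiation = initiation,
                 gu_stack = gu_stack, loop_penalty = loop_penalty),
            class = "nn_params")
}

#' Free energy of an aligned miRNA:target duplex
#'
#' Sums tabulated stacking energies over consecutive paired columns of the
#' alignment, adds the initiation penalty, and charges one fixed penalty per
#' interior loop/bulge event (a maximal run of unpaired or gapped columns
#' between two paired columns). G:U wobbles count as pairs.
#'
#' @param duplex a `duplex_alignment` from [align_duplex()], or a list with
#'   `tgt_align`, `mir_align`, `pairing`.
#' @param params [nn_params()].
#' @return free energy in kcal/mol (negative = stable).
#' @export
duplex_free_energy <- function(duplex, params = nn_params()) {
  sym <- chars(duplex$pairing)
  paired <- sym %in% c("|", ":")
  if (!any(paired)) stop("no duplex: pairing contains zero base pairs",
                         call. = FALSE)
  tgt <- chars(duplex$tgt_align)
  mir <- chars(duplex$mir_align)
  idx <- which(paired)
  dg <- params$initiation
  for (i in seq_along(idx)[-1]) {
    a <- idx[i - 1L]; b <- idx[i]
    if (b == a + 1L) {
      key <- paste0(tgt[a], tgt[b], "/", mir[a], mir[b])
      dg <- dg + if (sym[a] == "|" && sym[b] == "|") {
        val <- params$stack[key]
        if (is.na(val)) stop("unknown stack ", key, call. = FALSE)
        val
      } else {
        params$gu_stack
      }
    } else {
      dg <- dg + params$loop_penalty  # one interior loop/bulge event
    }
  }
  unname(dg)
}
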