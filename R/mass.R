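#' Monoisotopic mass table for the 20 canonical amino acids
#'
#' Residue masses are monoisotopic (Da); a peptide's neutral mass is the sum
#' of its residue masses plus one water. Leucine and isoleucine share the
#' same elemental composition and are therefore isobaric, which is the root
#' of the I/L ambiguity handled elsewhere in the package.
#'
#' @return A list with components `residues` (named numeric vector of the 20
#'   one-letter codes), `water` (mass of H2O, Da) and `proton` (mass of a
#'   proton, Da, used to convert neutral mass to singly protonated m/z).
#' @examples
#' tab <- mass_table()
#' tab$residues[["G"]]
#' @export
mass_table <- function() {
  residues <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  list(residues = residues, water = 18.010565, proton = 1.007276)
}

.assert_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(mass_table()$residues))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue code(s) in sequence '%s': %s",
                 sequence, paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  }
  chars
}

#' Neutral monoisotopic mass of a peptide
#'
#' @param sequence Amino-acid string (uppercase one-letter codes).
#' @param table Mass table, see [mass_table()].
#' @return Neutral monoisotopic mass in Da (residue masses + water).
#' @examples
#' compute_mass("DSGEGDFLAEGGGVR") # ~1464.648
#' @export
compute_mass <- function(sequence, table = mass_table()) {
  chars <- .assert_sequence(sequence)
  sum(table$residues[chars]) + table$water
}

#' Exoproteolytic children of a peptide sequence
#'
#' An exoprotease removes a single residue from the N- or C-terminus, so a
#' peptide of length >= 2 has at most two distinct exo products.
#'
#' @param sequence Amino-acid string.
#' @return Character vector of distinct child sequences (length 0 for a
#'   single residue, which cannot be degraded further).
#' @examples
#' exo_children("SANSNPAMAPRERKAGCKNFF")
#' exo_children("AA") # collapses to one child
#' @export
exo_children <- function(sequence) {
  .assert_sequence(sequence)
  n <- nchar(sequence)
  if (n < 2L) return(character(0L))
  unique(c(substr(sequence, 2L, n), substr(sequence, 1L, n - 1L)))
}

#' Enumerate endoproteolytic splits of a sequence
#'
#' Cut position `c` is 1-based and means "after residue c", so the products
#' are `sequence[1..c]` and `sequence[c+1..n]` for c = 1..n-1.
#'
#' @param sequence Amino-acid string of length >= 2.
#' @return Data frame with columns `prefix`, `suffix`, `cut` ordered by cut
#'   position.
#' @examples
#' endo_splits("GAV")
#' @export
endo_splits <- function(sequence) {
  .assert_sequence(sequence)
  n <- nchar(sequence)
  if (n < 2L) stop("endo splits require length >= 2", call. = FALSE)
  cuts <- seq_len(n - 1L)
  data.frame(
    prefix = substring(sequence, 1L, cuts),
    suffix = substring(sequence, cuts + 1L, n),
    cut = cuts,
    stringsAsFactors = FALSE
  )
}
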