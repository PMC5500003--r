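# Canonical human tau, longest isoform (2N4R, 441 residues). The in vitro
# constructs are subranges of this sequence: K18 = 244-372, the 187-residue
# C-terminal fragment ("dtau187") = 255-441, optionally carrying an
# N-terminal His6 tag.
.tau_4r2n <- paste0(
  "MAEPRQEFEVMEDHAGTYGLGDRKDQGGYTMHQDQEGDTDAGLKESPLQTPTEDGSEEPGSETSDAKSTP",
  "TAEDVTAPLVDEGAPGKQAAAQPHTEIPEGTTAEEAGIGDTPSLEDEAAGHVTQARMVSKSKDGTGSDDK",
  "KAKGADGKTKIATPRGAAPPGQKGQANATRIPAKTPPAPKTPPSSGEPPKSGDRSGYSSPGSPGTPGSRS",
  "RTPSLPTPPTREPKKVAVVRTPPKSPSSAKSRLQTAPVPMPDLKNVKSKIGSTENLKHQPGGGKVQIINK",
  "KLDLSNVQSKCGSKDNIKHVPGGGSVQIVYKPVDLSKVTSKCGSLGNIHHKPGGGQVEVKSEKLDFKDRV",
  "QSKIGSLDNITHVPGGGNKKIETHKLTFRENAKAKTDHGAEIVYKSPVVSGDTSPRHLSNVSSTGSIDMV",
  "DSPQLATLADEVSASLAKQGL"
)

.aa_alphabet <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Average residue masses (Da); free chain adds one water.
.aa_residue_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Construct a protein specification
#'
#' Bundles a name, a one-letter amino-acid sequence and an optional
#' N-terminal tag into the object the charge-balance functions consume.
#' The sequence (tag included) is validated against the 20 canonical
#' residues, naming the first offending position on failure.
#'
#' @param name Identifier for the construct.
#' @param sequence One-letter amino-acid string (non-empty).
#' @param tag Optional one-letter prefix fused N-terminally (e.g. a His6
#'   tag, `"MHHHHHH"`); `NULL` for none.
#'
#' @return An object of class `protein_spec`: a list with elements
#'   `name`, `sequence` (tag included), `core_sequence`, `tag` and
#'   `mass` (average molar mass, Da).
#' @examples
#' protein_spec("toy", "GGKK")
#' @export
protein_spec <- function(name, sequence, tag = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    rlang::abort("`sequence` must be a non-empty one-letter amino-acid string.")
  }
  full <- paste0(if (is.null(tag)) "" else tag, sequence)
  aa <- strsplit(full, "")[[1]]
  bad <- which(!aa %in% .aa_alphabet)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Invalid residue '%s' at position %d of '%s'.", aa[bad[1]], bad[1], name
    ))
  }
  mass <- protein_mass(full)
  stopifnot(mass > 0)
  structure(
    list(name = name, sequence = full, core_sequence = sequence,
         tag = tag, mass = mass),
    class = "protein_spec"
  )
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> %s: %d aa, %.1f Da%s\n",
              x$name, nchar(x$sequence), x$mass,
              if (is.null(x$tag)) "" else paste0(" (tag ", x$tag, ")")))
  invisible(x)
}

#' Average molar mass of a protein sequence
#'
#' Sums average residue masses and adds one water for the free chain.
#'
#' @param sequence One-letter amino-acid string or a [protein_spec()].
#' @return Molar mass in Da.
#' @examples
#' protein_mass("GG")
#' @export
protein_mass <- function(sequence) {
  if (inherits(sequence, "protein_spec")) sequence <- sequence$sequence
  aa <- strsplit(sequence, "")[[1]]
  m <- .aa_residue_mass[aa]
  if (anyNA(m)) {
    rlang::abort(sprintf("Invalid residue '%s' at position %d.",
                         aa[which(is.na(m))[1]], which(is.na(m))[1]))
  }
  sum(m) + 18.01528
}

#' Tau construct sequences and specifications
#'
#' `tau_sequence()` returns the one-letter sequence of one of the three
#' tau constructs used throughout the package: the full-length longest
#' isoform `"4R2N"` (residues 1-441), the four-repeat microtubule-binding
#' fragment `"K18"` (residues 244-372), and the C-terminal fragment
#' `"dtau187"` (residues 255-441). `tau_protein()` wraps the sequence in
#' a [protein_spec()], for `"dtau187"` optionally prefixing the His6
#' expression tag `"MHHHHHH"`.
#'
#' The His-tagged and tag-free forms of dtau187 differ by about 8% in
#' their predicted charge-to-mass ratio; see the package vignette for why
#' the charge-balance analyses default to the tag-free form.
#'
#' @param construct One of `"4R2N"`, `"K18"`, `"dtau187"`.
#' @param his_tag For `"dtau187"` only: prefix the `"MHHHHHH"` tag?
#'   Default `FALSE` (charge calculations on the expressed polypeptide
#'   core).
#'
#' @return `tau_sequence()` a character scalar; `tau_protein()` a
#'   [protein_spec()].
#' @examples
#' nchar(tau_sequence("4R2N"))
#' tau_protein("dtau187", his_tag = TRUE)
#' @export
tau_sequence <- function(construct = c("4R2N", "K18", "dtau187")) {
  construct <- match.arg(construct)
  switch(construct,
    "4R2N"    = .tau_4r2n,
    "K18"     = substr(.tau_4r2n, 244, 372),
    "dtau187" = substr(.tau_4r2n, 255, 441)
  )
}

#' @rdname tau_sequence
#' @export
tau_protein <- function(construct = c("4R2N", "K18", "dtau187"),
                        his_tag = FALSE) {
  construct <- match.arg(construct)
  tag <- if (construct == "dtau187" && his_tag) "MHHHHHH" else NULL
  protein_spec(construct, tau_sequence(construct), tag = tag)
}

#' Read a protein specification from a FASTA file
#'
#' Reads the first record of a FASTA file into a [protein_spec()].
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param tag Optional N-terminal tag, as in [protein_spec()].
#' @return A [protein_spec()].
#' @export
read_protein_fasta <- function(path, tag = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("read_protein_fasta() requires the Biostrings package.")
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) rlang::abort("No FASTA record found.")
  name <- sub("\\s.*$", "", names(aa)[1])
  protein_spec(name, as.character(aa[[1]]), tag = tag)
}
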