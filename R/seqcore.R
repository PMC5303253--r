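#' CodingSequence: a validated protein-coding nucleotide sequence
#'
#' S4 container for a coding sequence (CDS). Input may use the RNA alphabet
#' (U) and lower case; it is canonicalized to upper-case DNA. The sequence
#' must be a non-empty multiple of three with no internal stop codon; a
#' trailing stop codon is accepted, recorded, and excluded from all
#' codon-level feature computations (CAI, RSCU). Ambiguity codes (N etc.)
#' are rejected.
#'
#' @slot sequence canonical upper-case DNA string (including a trailing stop
#'   codon if one was present).
#' @slot codons character vector of sense codons (trailing stop dropped).
#' @slot hasTrailingStop logical flag.
#' @seealso [codingSequence()], [translate()], [codons()]
#' @export
setClass("CodingSequence",
  representation(
    sequence = "character",
    codons = "character",
    hasTrailingStop = "logical"
  )
)

setValidity("CodingSequence", function(object) {
  if (length(object@sequence) != 1L) return("sequence must be a single string")
  if (nchar(object@sequence) %% 3L != 0L) {
    return("nucleotide length must be a multiple of 3")
  }
  if (grepl("[^ACGT]", object@sequence)) {
    return("sequence contains characters outside A/C/G/T")
  }
  TRUE
})

#' Construct a CodingSequence
#'
#' @param x single character string over A/C/G/T/U, case-insensitive.
#' @return A [CodingSequence-class] object.
#' @examples
#' g <- codingSequence("atguggTAA")  # Met-Trp + stop
#' codons(g)
#' translate(g)
#' @export
codingSequence <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("'x' must be a single character string")
  }
  seq <- canonicalizeNucleotides(x)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (nchar(seq) %% 3L != 0L) {
    stop("nucleotide length (", nchar(seq), ") is not a multiple of 3")
  }
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) > 0L && nzchar(bad)) {
    stop("invalid nucleotide '", bad, "' (ambiguity codes are not supported)")
  }
  cod <- splitCodons(seq)
  code <- geneticCode()
  isStop <- code$codonToAa[cod] == "*"
  n <- length(cod)
  if (any(isStop[-n])) {
    stop("internal stop codon at codon ", which(isStop)[1L])
  }
  trailing <- isStop[n]
  if (trailing) cod <- cod[-n]
  if (length(cod) == 0L) stop("sequence contains only a stop codon")
  new("CodingSequence", sequence = seq, codons = cod,
      hasTrailingStop = unname(trailing))
}

# fast internal constructor: 'cod' must already be valid sense codons
.cdsFromCodons <- function(cod) {
  new("CodingSequence", sequence = paste(cod, collapse = ""),
      codons = cod, hasTrailingStop = FALSE)
}

#' Canonicalize a nucleotide string (RNA to DNA, upper case)
#'
#' Idempotent: applying it twice equals applying it once.
#' @param x character vector of sequences.
#' @return character vector, upper case with U replaced by T.
#' @export
canonicalizeNucleotides <- function(x) {
  chartr("U", "T", toupper(x))
}

splitCodons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

#' Accessors for CodingSequence
#'
#' \code{codons} returns the sense codons (trailing stop excluded);
#' \code{ntSequence} the full canonical nucleotide string;
#' \code{nCodons} the length in sense codons \eqn{L(g)};
#' \code{ntLength} the length in nucleotides;
#' \code{hasTrailingStop} whether a trailing stop codon was present.
#'
#' @param x a [CodingSequence-class].
#' @return See individual descriptions.
#' @name CodingSequence-accessors
#' @aliases codons ntSequence nCodons ntLength hasTrailingStop
#' @examples
#' g <- codingSequence("ATGTGG")
#' nCodons(g)
NULL

#' @rdname CodingSequence-accessors
#' @export
codons <- function(x) x@codons

#' @rdname CodingSequence-accessors
#' @export
ntSequence <- function(x) x@sequence

#' @rdname CodingSequence-accessors
#' @export
nCodons <- function(x) length(x@codons)

#' @rdname CodingSequence-accessors
#' @export
ntLength <- function(x) nchar(x@sequence)

#' @rdname CodingSequence-accessors
#' @export
hasTrailingStop <- function(x) x@hasTrailingStop

setMethod("show", "CodingSequence", function(object) {
  n <- nCodons(object)
  preview <- if (ntLength(object) > 60L) {
    paste0(substr(object@sequence, 1L, 57L), "...")
  } else object@sequence
  cat("CodingSequence of", n, "codons",
      if (object@hasTrailingStop) "(+ trailing stop)" else "", "\n")
  cat(" ", preview, "\n")
})

#' Translate a coding sequence to protein
#'
#' Standard genetic code; the trailing stop codon, if present, is dropped.
#' Internal stops are impossible by construction of
#' [CodingSequence-class].
#'
#' @param x a [CodingSequence-class].
#' @param genetic.code,no.init.codon,if.fuzzy.codon ignored for this class;
#'   the standard code is always used and fuzzy codons cannot occur.
#' @return Single character string over the 20-letter amino-acid alphabet.
#' @examples
#' translate(codingSequence("ATGTGGTAA"))  # "MW"
#' @importMethodsFrom Biostrings translate
#' @export
setMethod("translate", "CodingSequence",
          function(x, genetic.code, no.init.codon, if.fuzzy.codon) {
  paste(geneticCode()$codonToAa[x@codons], collapse = "")
})

#' Validate a protein sequence
#'
#' @param x single string over the 20-letter amino-acid alphabet
#'   (case-insensitive).
#' @return The validated upper-case string, invisibly classed as before.
#' @export
proteinSequence <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("'x' must be a single character string")
  }
  p <- toupper(x)
  if (nchar(p) == 0L) stop("empty protein sequence")
  bad <- regmatches(p, regexpr(sprintf("[^%s]", paste(.aaAlphabet(), collapse = "")), p))
  if (length(bad) > 0L && nzchar(bad)) {
    stop("invalid amino-acid symbol '", bad, "'")
  }
  p
}

#' Read a FASTA file
#'
#' Reads wrapped or unwrapped FASTA. Record ids are the first
#' whitespace-delimited token of each header. Empty files and duplicated ids
#' are errors.
#'
#' @param path file path.
#' @return Named character vector of raw sequences (no validation; see
#'   [readCdsSet()] / [readProteinSet()] for validated readers).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- as.character(set)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector (or named list of
#'   [CodingSequence-class]) of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
  if (is.list(records)) {
    records <- vapply(records, function(r) {
      if (is(r, "CodingSequence")) ntSequence(r) else as.character(r)
    }, character(1))
  }
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a FASTA file of coding sequences
#'
#' @param path file path.
#' @return Named list of [CodingSequence-class] objects.
#' @export
readCdsSet <- function(path) {
  raw <- readFasta(path)
  out <- lapply(seq_along(raw), function(i) {
    tryCatch(codingSequence(raw[[i]]),
             error = function(e) stop("record '", names(raw)[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(out) <- names(raw)
  out
}

#' Read a FASTA file of protein sequences
#'
#' @param path file path.
#' @return Named character vector of validated protein sequences.
#' @export
readProteinSet <- function(path) {
  raw <- readFasta(path)
  out <- vapply(seq_along(raw), function(i) {
    tryCatch(proteinSequence(raw[[i]]),
             error = function(e) stop("record '", names(raw)[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  names(out) <- names(raw)
  out
}
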