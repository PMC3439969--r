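## The 21-pattern PEM catalog and its mapping onto 19 architecture codes.
## Pattern labels H1..H11 are high-confidence, Q1..Q10 questionable; two
## pairs of patterns share an architecture code (Q1/Q7 -> VNTR,
## Q2/Q3 -> DEL_INS), so 21 patterns map onto 19 codes.

.pem_table <- data.frame(
  pattern = c(paste0("H", 1:11), paste0("Q", 1:10)),
  confidence = c(rep("high", 11), rep("questionable", 10)),
  code = c("DEL_UNIQUE", "DEL_REPEAT", "DEL_NML_DEL", "INV", "DEL_INV",
           "INS_UNIQUE", "INS_REPEAT", "TANDEM_DUP", "INV_TANDEM_DUP",
           "DISPERSED_GAIN", "SV_IN_GAIN",
           "VNTR", "DEL_INS", "DEL_INS", "LARGE_DEL", "LINKED_GAIN",
           "RETROGENE_FALSE_DEL", "VNTR", "INV_INS", "INV_LINKED_GAIN",
           "RETROGENE_FALSE_INV"),
  description = c(
    "Deletion of unique sequence",
    "Deletion of repeat sequence (e.g. LINE, SINE, ERV)",
    "Deletions separated by small normal copy (Del+Nml+Del)",
    "Typical inversion",
    "Inversion co-occurring with deletion(s)",
    "Insertion of unique (de novo) sequence",
    "Insertion of repeat sequence (e.g. LINE, SINE, ERV)",
    "Tandem duplication",
    "Inverted tandem duplication",
    "Dispersed copy number gains",
    "Deletion or inversion within copy number gain",
    "Deletion due to microsatellite size polymorphism",
    "Deletion of unique sequence co-occurring with insertion",
    "Deletion of repeat sequence co-occurring with insertion",
    "Large deletion",
    "Linked small gain causing a false deletion",
    "False deletion due to retrotransposed pseudogene",
    "Deletion due to VNTR",
    "Inversion co-occurring with insertion",
    "Inverted linked small gain causing a false inversion",
    "False inversion due to inverted retrotransposed pseudogene"),
  complexity = c("simple", "simple", "simple", "simple", "complex",
                 "simple", "simple", "simple", "complex", "simple",
                 "complex",
                 "simple", "complex", "complex", "simple", "simple",
                 "false", "VNTR", "complex", "simple", "false"),
  stringsAsFactors = FALSE
)

#' The catalog of 21 paired-end mapping patterns
#'
#' Returns the full pattern taxonomy: 11 high-confidence ("H") and 10
#' questionable ("Q") PEM patterns, the architecture code each implies, a
#' short description, and the simple/complex/false/VNTR adjudication of the
#' underlying SV.
#'
#' @return A data.frame with columns `pattern`, `confidence`, `code`,
#'   `description`, `complexity`.
#' @export
pem_pattern_table <- function() .pem_table

#' Architecture codes known to the simulator and classifier
#'
#' The 19 distinct codes implied by the 21 PEM patterns; 17 describe true
#' rearrangements and 2 (`RETROGENE_FALSE_DEL`, `RETROGENE_FALSE_INV`)
#' describe retrogene artifacts that mimic SV signatures.
#'
#' @return Character vector of codes.
#' @export
sv_codes <- function() unique(.pem_table$code)

#' Simple/complex/false/VNTR adjudication for an architecture code
#'
#' @param code One or more architecture codes from [sv_codes()].
#' @return Character vector of complexities.  Codes shared by two patterns
#'   (`VNTR`, `DEL_INS`) have a single code-level complexity (`"VNTR"` and
#'   `"complex"` respectively).
#' @export
sv_complexity <- function(code) {
  m <- .pem_table[match(code, .pem_table$code), "complexity"]
  if (anyNA(m)) stop("unknown architecture code: ",
                     paste(code[is.na(m)], collapse = ", "))
  ## code-level override: the VNTR code adjudicates as VNTR even though the
  ## microsatellite pattern Q1 is listed as simple at pattern level
  m[code == "VNTR"] <- "VNTR"
  m
}

#' @rdname sv_complexity
#' @param pattern A PEM pattern label (`"H1"`..`"H11"`, `"Q1"`..`"Q10"`).
#' @export
pattern_complexity <- function(pattern) {
  i <- match(pattern, .pem_table$pattern)
  if (anyNA(i)) stop("unknown PEM pattern: ",
                     paste(pattern[is.na(i)], collapse = ", "))
  .pem_table$complexity[i]
}

#' @rdname sv_complexity
#' @export
pattern_code <- function(pattern) {
  i <- match(pattern, .pem_table$pattern)
  if (anyNA(i)) stop("unknown PEM pattern: ",
                     paste(pattern[is.na(i)], collapse = ", "))
  .pem_table$code[i]
}

## default pattern label for an architecture code (the high-confidence
## pattern where one exists)
code_pattern <- function(code) {
  i <- match(code, .pem_table$code)  # first match = H pattern when present
  .pem_table$pattern[i]
}
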