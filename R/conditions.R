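# Structured rejection/error conditions with stable reason codes.
# Reason codes surfaced to users: NONCANONICAL, GROOVE_LIGAND, UNPARSEABLE,
# NO_ALLELE, BAD_LENGTH (filter level); NO_PEPTIDE / NO_RECEPTOR are emitted
# at the extraction level and mapped by the filter.

reject <- function(reason, message, call = NULL) {
  cond <- structure(
    class = c("anchormod_rejection", "error", "condition"),
    list(message = sprintf("[%s] %s", reason, message),
         call = call, reason = reason)
  )
  stop(cond)
}

#' Reason code of a rejection condition
#' @param cond a condition object.
#' @return the reason code string, or `NA` if not a rejection.
#' @export
rejection_reason <- function(cond) {
  if (inherits(cond, "anchormod_rejection")) cond$reason else NA_character_
}
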