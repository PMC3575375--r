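# Condition classes shared across the package. The CLI maps them to exit
# codes: phylogeny -> 3, capped run -> 4, format/domain/invariant -> 5.

abort_format <- function(msg, ...) {
  abort(msg, class = "coalexact_format_error", ...)
}

abort_domain <- function(msg, ...) {
  abort(msg, class = "coalexact_domain_error", ...)
}

abort_invariant <- function(msg, ...) {
  abort(msg, class = c("coalexact_invariant_error", "coalexact_domain_error"), ...)
}

abort_phylogeny <- function(msg, witness = NULL, ...) {
  abort(msg, class = "coalexact_phylogeny_error", witness = witness, ...)
}

abort_capped <- function(msg, ...) {
  abort(msg, class = "coalexact_capped_error", ...)
}

warn_capped <- function(msg, ...) {
  warn(msg, class = "coalexact_capped_run", ...)
}
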