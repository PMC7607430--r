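# Structured parse errors: every syntax failure carries a machine-readable
# code and a 0-based character offset into the input string, so validate()
# can surface them as diagnostics instead of bare messages.

lc_error <- function(code, offset, message) {
  cond <- structure(
    class = c("licorr_parse_error", "error", "condition"),
    list(message = sprintf("%s at offset %d: %s", code, offset, message),
         call = NULL, code = code, offset = offset, detail = message))
  stop(cond)
}

is_upper <- function(ch) ch >= "A" & ch <= "Z"
is_digit <- function(ch) ch >= "1" & ch <= "9"
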