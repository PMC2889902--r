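# internal helpers shared across modules

# rbind a list of data.frame rows; NULL when empty (callers supply the
# empty-frame fallback)
.rbindRows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
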