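# rbind a list of data-frame rows, ignoring NULLs; NULL when nothing remains
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
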