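# internal helpers

geo_mean <- function(x) exp(mean(log(x)))

# sample SD with n-1 denominator, kept explicit for readability at call sites
sd1 <- function(x) stats::sd(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# coerce ct_matrix / plain matrix input, optionally attaching a group vector
as_ct_input <- function(x, group = NULL) {
  if (inherits(x, "ct_matrix")) return(x)
  if (is.matrix(x)) return(ct_matrix(x, group = group))
  stopf("expected a 'ct_matrix' or a numeric matrix, got <%s>", class(x)[1])
}
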