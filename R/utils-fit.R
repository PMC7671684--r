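# Internal Levenberg-Marquardt front end.
#
# nlsLM's model constructor occasionally rejects a perfectly usable start
# point ("singular gradient matrix at initial parameter estimates") when
# the finite-difference Jacobian happens to be rank-deficient at exactly
# that point. The fit itself is well posed, so retry from slightly nudged
# start values before giving up.
safe_nlsLM <- function(formula, data, start, ...) {
  args <- c(list(formula, data = data, start = start), list(...))
  first_err <- NULL
  for (f in c(1, 1.005, 0.995, 1.02)) {
    st <- lapply(start, function(v) v * f + (f - 1) * 1e-6)
    args$start <- st
    r <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
    if (!inherits(r, "error")) return(r)
    if (is.null(first_err)) first_err <- r
    if (!grepl("singular gradient", conditionMessage(r))) break
  }
  stop(first_err)
}
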