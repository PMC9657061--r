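# enumerations reused across test files, computed once per run
isaw_table <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <- enumerate_isaw(n)
    cache[[key]]
  }
})

isaw_poly <- function(n) contact_polynomials(isaw_table(n))

# cubic-lattice self-avoiding-walk counts (six times the fixed-first-step
# totals), used to cross-check enumeration totals
SAW_COUNTS <- c(6, 30, 150, 726, 3534, 16926, 81390, 387966, 1853886,
                8809878, 41934150, 198842742, 943974510)
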