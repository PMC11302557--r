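# shared internal helpers

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs the
# session stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

isPalindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

twoSidedNormalP <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

emptyDropLog <- function() {
  data.frame(variant_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}
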