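# small shared fixtures, built once per test run

tinyGradients <- makeGradients(120, 5, seed = 11)

tinyTruth <- plantedTruth()

# a GradientSet with exactly two parcels per network, values 1..14
handGradients <- local({
  v <- matrix(as.numeric(1:14), ncol = 1,
              dimnames = list(sprintf("p%04d", 1:14), "gradient_1"))
  GradientSet(v, rep(yeoNetworkNames(), each = 2), "hand-built fixture")
})

# balanced two-condition within-participant data with planted subject
# intercepts; offset is added to condition "b"
pairedData <- function(n, offset = 0, subjectSd = 0.5, noiseSd = 0.5,
                       seed = 1) {
  set.seed(seed)
  intercepts <- rnorm(n, sd = subjectSd)
  data.frame(participant = rep(sprintf("s%03d", seq_len(n)), each = 2),
             condition = rep(c("a", "b"), n),
             y = rep(intercepts, each = 2) +
               rep(c(0, offset), n) + rnorm(2 * n, sd = noiseSd))
}
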