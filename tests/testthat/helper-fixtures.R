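# Small fixtures built in code; nothing is read from disk except what a
# test writes itself.

make_series <- function(voxels, id = "S1", patient = "P1",
                        sequence = "T1WI-SE", region = "brain") {
  mr_series(voxels, id, patient, sequence, region)
}

# A lognormal phantom series with reproducible voxels
lognormal_series <- function(n = 5000, meanlog = 6, sdlog = 0.5, seed = 1,
                             gain = 1, offset = 0, ...) {
  set.seed(seed)
  make_series(gain * rlnorm(n, meanlog, sdlog) + offset, ...)
}

# Random strictly-increasing 11-knot landmark vector
random_landmarks <- function(seed = 1, lo = 10, hi = 4000) {
  set.seed(seed)
  sort(runif(11, lo, hi))
}

# A scale object with given nodes (bypasses training)
scale_with_nodes <- function(nodes, sequence = "T1WI-SE", region = "brain") {
  structure(list(sequence = sequence, region = region,
                 percentiles = landmark_percentiles, nodes = nodes,
                 n_images = 1L),
            class = "standard_scale")
}

default_scale_nodes <- function() c(1, seq(10, 90, by = 10), 100)

toy_records <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2"),
    series_id = c("S1", "S1", "S2"),
    sequence = c("T1WI-SE", "T1WI-SE", "T2WI-TSE"),
    region = c("brain", "brain", "pelvis"),
    operator = c(1L, 2L, 3L),
    WL = c(400, 420, 900),
    WW = c(800, 760, 1500),
    frame = "native",
    stringsAsFactors = FALSE)
}

# Small true-parameter set shared by model tests
toy_truth <- function(I = 3, J = 2) {
  list(beta = rbind(c(48, 60), c(-5, 8), c(6, -10))[seq_len(I), , drop = FALSE],
       tau = c(3, 5, 4, 6, 3.5)[seq_len(J)],
       Sigma = list(cov_from(2.5, 4, 0.5), cov_from(3, 5, 0.35),
                    cov_from(2, 3.5, 0.6))[seq_len(I)])
}

fast_sampler <- function() sampler_settings(chains = 2, warmup = 300,
                                            draws = 500)
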