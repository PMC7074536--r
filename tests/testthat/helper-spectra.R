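# Builders and the brute-force peak-matching oracle used by the
# networking tests.

# one-row spectrum from bare vectors
spec1 <- function(mz, intensity = rep(1, length(mz)), precursor = max(mz) + 1,
                  id = "s", rt = NA_real_) {
  fragment_spectra(
    scan_id = id, precursor_mz = precursor,
    peaks = list(data.frame(mz = mz, intensity = intensity)), rt = rt
  )
}

# Exhaustive modified-cosine: enumerates every one-to-one assignment of
# candidate peak pairs (direct or precursor-shifted) and returns the
# maximal cosine. Independent of the package's matcher.
oracle_modified_cosine <- function(a, b, frag_tol = 0.05) {
  pa <- a$peaks[[1]]; pb <- b$peaks[[1]]
  if (nrow(pa) == 0 || nrow(pb) == 0) return(0)
  shift <- a$precursor_mz - b$precursor_mz
  wa <- sqrt(pa$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(pb$intensity); wb <- wb / sqrt(sum(wb^2))
  cand <- list()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      d <- pa$mz[i] - pb$mz[j]
      if (abs(d) <= frag_tol || abs(d - shift) <= frag_tol) {
        cand[[length(cand) + 1]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  if (length(cand) == 0) return(0)
  best <- 0
  enumerate <- function(k, used_i, used_j, acc) {
    if (acc > best) best <<- acc
    if (k > length(cand)) return(invisible())
    enumerate(k + 1, used_i, used_j, acc)
    p <- cand[[k]]
    if (!(p[1] %in% used_i) && !(p[2] %in% used_j)) {
      enumerate(k + 1, c(used_i, p[1]), c(used_j, p[2]), acc + p[3])
    }
  }
  enumerate(1, integer(0), integer(0), 0)
  min(best, 1)
}

# random small spectrum for property tests
random_spectrum <- function(n_peaks, id = "r") {
  mz <- sort(runif(n_peaks, 80, 600))
  spec1(mz, runif(n_peaks, 10, 1000), precursor = runif(1, 600, 700),
        id = id)
}
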