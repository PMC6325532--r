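# Shared fixtures, built in code at test time.

# small mixed phantom reused across stripe/profile/coloc tests
test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_phantom("mixed", c(192L, 256L, 3L), seed = 42L)
    }
    cache
  }
})

# sparse blob image for registration tests
blob_image <- function(n = 96L, n_blobs = 30L, seed = 3L) {
  img <- matrix(0, n, n)
  with_test_seed(seed, {
    for (i in seq_len(n_blobs)) {
      y <- sample(10:(n - 10), 1); x <- sample(10:(n - 10), 1)
      img[y + (-2:2), x + (-2:2)] <- img[y + (-2:2), x + (-2:2)] +
        exp(-outer((-2:2)^2, (-2:2)^2, "+") / 4) * runif(1, 1, 3)
    }
  })
  img
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
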