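# Independent oracles and small fixtures shared across test files.

# Recursive coancestry (kinship) oracle, memoized. A = 2 * kinship; written
# independently of the tabular recursion in the package.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- ped$si; di <- ped$di
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { k <- i; i <- j; j <- k }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) 0.5 * (1 + phi(si[i], di[i]))
    else 0.5 * (phi(i, si[j]) + phi(i, di[j]))
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- 2 * phi(i, j)
    A[j, i] <- A[i, j]
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# random valid pedigree with overlapping generations, <= n_max individuals
random_pedigree <- function(n_max = 30) {
  n_founder <- sample(4:8, 1)
  sex <- c(rep("M", ceiling(n_founder / 2)),
           rep("F", floor(n_founder / 2)))
  id <- sprintf("i%02d", seq_len(n_founder))
  sire <- dam <- rep(NA_character_, n_founder)
  cohort <- rep(1, n_founder)
  while (length(id) < n_max) {
    males <- id[sex == "M"]; females <- id[sex == "F"]
    if (!length(males) || !length(females)) break
    k <- length(id) + 1L
    id <- c(id, sprintf("i%02d", k))
    sire <- c(sire, sample(rep(males, 2), 1))
    dam <- c(dam, sample(rep(females, 2), 1))
    sex <- c(sex, sample(c("M", "F"), 1))
    cohort <- c(cohort, max(cohort) + sample(0:1, 1))
    if (runif(1) < 0.1) break
  }
  validate_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                               cohort = cohort))
}

# five-member pedigree whose last member is the offspring of a full-sib mating
fullsib_ped <- function() {
  validate_pedigree(data.frame(
    id = c("s", "d", "b1", "b2", "x"),
    sire = c(NA, NA, "s", "s", "b1"),
    dam = c(NA, NA, "d", "d", "b2"),
    sex = c("M", "F", "M", "F", "F"),
    cohort = c(1, 1, 2, 2, 3)))
}

# small synthetic dataset for fitting tests (about 300-450 records)
tiny_dataset <- function(seed = 1, ...) {
  simulate_population(sim_config(seed = seed, years = 16, n_founder_f = 55,
                                 n_founder_m = 35, ...))
}

# fabricate an evd_chain-like object from a named list of sample vectors
fake_chain <- function(..., bv = NULL) {
  cols <- list(...)
  samples <- do.call(cbind, cols)
  colnames(samples) <- names(cols)
  structure(list(samples = samples, bv = bv, spec_label = "fake",
                 prior = "ig", seed = 0L, spec_hash = 0), class = "evd_chain")
}

# a lazily built, memoized univariate fit on a shared tiny dataset
.shared <- new.env(parent = emptyenv())
shared_uni_fit <- function() {
  if (is.null(.shared$uni)) {
    ds <- tiny_dataset(seed = 42)
    ped <- prune_pedigree(ds$pedigree,
                          unique(c(ds$records$id, ds$fitness$id)))
    fit <- suppressWarnings(
      fit_model(spec_univariate(chain = fast_chain(2200, 500, 4, seed = 3)),
                ds, ped))
    .shared$uni <- list(ds = ds, ped = ped, fit = fit)
  }
  .shared$uni
}
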