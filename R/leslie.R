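#' Row/column layout of the stacked stage-age vector
#'
#' The state vector stacks brood ages `1..D_b`, then nurse ages
#' `1..D_n`, then forager ages `1..D_f`.  This helper returns the
#' mapping from (stage, age) to position.
#'
#' @param structure A [stage_structure()].
#' @return A `data.frame` with columns `stage`, `age`, `index`.
#' @export
block_index <- function(structure) {
  stopifnot(inherits(structure, "stage_structure"))
  data.frame(
    stage = rep(c("brood", "nurse", "forager"),
                times = c(structure$brood_days, structure$nurse_max_days,
                          structure$forager_max_days)),
    age = c(seq_len(structure$brood_days), seq_len(structure$nurse_max_days),
            seq_len(structure$forager_max_days)),
    index = seq_len(structure$brood_days + structure$nurse_max_days +
                      structure$forager_max_days))
}

#' Build the colony projection (Leslie) matrix
#'
#' Assembles the square nonnegative matrix `M` whose application to the
#' stacked (brood, nurse, forager) age vector advances the colony one
#' day, reproducing the three stage recursions exactly:
#' \itemize{
#'   \item brood age 1 receives `r = p/c` from every forager age class
#'     (brood production is food-limited, not fecundity-limited);
#'   \item brood ages `2..D_b` survive with `s_b`; brood age `D_b`
#'     emerges into nurse age 1 with `s_b`;
#'   \item nurse age `i` survives with its Gompertz-Makeham survival
#'     `s_n,i-1` and stays a nurse with probability `1 - g`;
#'   \item forager age 1 recruits `s_n,j * g` from every nurse age `j`
#'     (nurses in the terminal class included; non-transitioning
#'     terminal nurses are removed);
#'   \item forager ages `2..D_f` survive with `s_f,i-1`; foragers
#'     beyond `D_f` are removed.
#' }
#' No other entries are nonzero.
#'
#' @param params A valid [colony_params()] object.
#' @return A dense matrix of class `leslie_matrix` with dimnames like
#'   `"nurse_17"`, and attributes `structure` and `params`.
#' @examples
#' M <- build_leslie_matrix(default_scenarios()$summer$params)
#' dim(M)           # 160 x 160 for the default stage structure
#' sum(M != 0)      # 297 structural nonzeros
#' @export
build_leslie_matrix <- function(params) {
  assert_valid_params(params)
  st <- params$structure
  Db <- st$brood_days; Dn <- st$nurse_max_days; Df <- st$forager_max_days
  n <- Db + Dn + Df
  r <- provisioning_ratio(params)
  sn <- gm_schedule(params$nurse_gm, "nurse", Dn)$s
  sf <- gm_schedule(params$forager_gm, "forager", Df)$s

  M <- matrix(0, n, n)
  idx <- block_index(st)
  dimnames(M) <- rep(list(paste(idx$stage, idx$age, sep = "_")), 2)

  M[1, Db + Dn + seq_len(Df)] <- r
  if (Db >= 2) for (i in 2:Db) M[i, i - 1] <- params$s_b
  M[Db + 1, Db] <- params$s_b
  if (Dn >= 2) for (i in 2:Dn) M[Db + i, Db + i - 1] <- sn[i - 1] * (1 - params$g)
  M[Db + Dn + 1, Db + seq_len(Dn)] <- sn * params$g
  if (Df >= 2) for (i in 2:Df) M[Db + Dn + i, Db + Dn + i - 1] <- sf[i - 1]

  structure(M, class = c("leslie_matrix", "matrix", "array"),
            structure = st, params = params)
}

# internal: spectral radius only (fast path for perturbation elasticities)
spectral_radius <- function(M) {
  max(Mod(eigen(unclass(M), only.values = TRUE)$values))
}

#' Dominant eigenvalue, stable stage distribution and reproductive values
#'
#' Computes the colony growth rate `lam` (dominant eigenvalue, the
#' asymptotic per-day growth factor), the right eigenvector normalized
#' to sum 1 (stable stage-age distribution) and the left eigenvector
#' normalized so its inner product with the stable distribution is 1
#' (reproductive values).  For these primitive-like matrices the
#' dominant eigenvalue is real, simple and positive; the imaginary
#' residual of the computed value must be below 1e-9 or an error is
#' raised.  When `p = 0` the life-cycle graph is acyclic, the matrix is
#' nilpotent and the function returns `lam = 0` with eigenvectors
#' flagged undefined (`defined = FALSE`).
#'
#' A power-iteration fallback covers the (never observed at default
#' tolerances) case of LAPACK non-convergence.
#'
#' @param M A [build_leslie_matrix()] result (or any square matrix).
#' @return An object of class `eigen_triple`: list with `lam`,
#'   `stable_dist`, `repro_values`, `defined`.
#' @export
eigen_analysis <- function(M) {
  A <- unclass(M)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (is.null(ev)) return(power_iteration_triple(A))
  # for imprimitive (periodic) life cycles several eigenvalues share the
  # maximal modulus; Perron-Frobenius guarantees a real nonnegative one,
  # which is the growth rate
  mods <- Mod(ev$values)
  cand <- which(mods >= max(mods) * (1 - 1e-9))
  k <- cand[which.max(Re(ev$values[cand]))]
  lam_c <- ev$values[k]
  if (Mod(lam_c) < 1e-12) {
    return(structure(list(lam = 0, stable_dist = NULL, repro_values = NULL,
                          defined = FALSE), class = "eigen_triple"))
  }
  if (abs(Im(lam_c)) >= 1e-9)
    stop("dominant eigenvalue has non-negligible imaginary part: ",
         format(Im(lam_c)))
  lam <- Re(lam_c)
  w <- Re(ev$vectors[, k])
  if (sum(w) < 0) w <- -w
  w[w < 0 & w > -1e-12] <- 0
  w <- w / sum(w)
  evl <- eigen(t(A))
  modl <- Mod(evl$values)
  candl <- which(modl >= max(modl) * (1 - 1e-9))
  kl <- candl[which.max(Re(evl$values[candl]))]
  v <- Re(evl$vectors[, kl])
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  v <- v / sum(v * w)
  structure(list(lam = lam, stable_dist = w, repro_values = v,
                 defined = TRUE), class = "eigen_triple")
}

# internal: power iteration on M and t(M); fallback only
power_iteration_triple <- function(A, tol = 1e-12, maxit = 100000L) {
  n <- nrow(A)
  pi_one <- function(B) {
    x <- rep(1 / n, n)
    lam <- 0
    for (i in seq_len(maxit)) {
      y <- B %*% x
      s <- sum(abs(y))
      if (s < 1e-300) return(list(lam = 0, vec = NULL))
      y <- as.vector(y) / s
      if (max(abs(y - x)) < tol) {
        return(list(lam = s, vec = y))
      }
      x <- y
      lam <- s
    }
    list(lam = lam, vec = x)
  }
  r1 <- pi_one(A)
  if (r1$lam == 0 || is.null(r1$vec)) {
    return(structure(list(lam = 0, stable_dist = NULL, repro_values = NULL,
                          defined = FALSE), class = "eigen_triple"))
  }
  r2 <- pi_one(t(A))
  w <- r1$vec / sum(r1$vec)
  v <- r2$vec / sum(r2$vec * w)
  structure(list(lam = r1$lam, stable_dist = w, repro_values = v,
                 defined = TRUE), class = "eigen_triple")
}

#' @export
print.eigen_triple <- function(x, ...) {
  cat(sprintf("dominant eigenvalue (daily colony growth rate): %.8f\n",
              x$lam))
  if (!x$defined)
    cat("eigenvectors undefined (nilpotent matrix, no reproductive loop)\n")
  invisible(x)
}

#' Expected adult worker lifespan in days
#'
#' Expected number of days survived as an adult for a worker entering
#' nurse age 1, by absorbing-chain summation.  A nurse at age `i`
#' survives the day with probability `s_n,i`, then transitions to
#' forager age 1 with probability `g`; a forager at age `i` survives
#' with `s_f,i`.  Survivors of the terminal nurse class that do not
#' transition, and of the terminal forager class, are removed
#' (truncation counts as death).
#'
#' @param params A valid [colony_params()] object.
#' @return Expected adult lifespan in days.
#' @examples
#' sapply(default_scenarios(), function(s) expected_adult_lifespan(s$params))
#' @export
expected_adult_lifespan <- function(params) {
  assert_valid_params(params)
  st <- params$structure
  sn <- gm_schedule(params$nurse_gm, "nurse", st$nurse_max_days)$s
  sf <- gm_schedule(params$forager_gm, "forager", st$forager_max_days)$s
  g <- params$g
  # P(still a nurse at start of age i), then survive that day with sn[i]
  pn <- cumprod(c(1, (sn * (1 - g))[-st$nurse_max_days]))
  nurse_days <- sum(pn * sn)
  p_enter_forager <- sum(pn * sn * g)
  pf <- cumprod(c(1, sf[-st$forager_max_days]))
  forager_days <- sum(pf * sf)
  nurse_days + p_enter_forager * forager_days
}

#' Export a Leslie matrix as dense CSV
#'
#' @param M A `leslie_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_leslie_csv <- function(M, path) {
  utils::write.csv(as.data.frame(unclass(M)), path, row.names = TRUE)
  invisible(path)
}

#' Export a Leslie matrix in sparse triplet form
#'
#' Writes `row,col,value` triplets of the structural nonzeros, preceded
#' by comment lines recording the block layout.
#'
#' @param M A `leslie_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_leslie_triplets <- function(M, path) {
  st <- attr(M, "structure")
  nz <- which(unclass(M) != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# block layout: brood 1..%d, nurse %d..%d, forager %d..%d",
    st$brood_days, st$brood_days + 1, st$brood_days + st$nurse_max_days,
    st$brood_days + st$nurse_max_days + 1,
    st$brood_days + st$nurse_max_days + st$forager_max_days), con)
  writeLines("row,col,value", con)
  writeLines(sprintf("%d,%d,%.17g", nz[, 1], nz[, 2],
                     unclass(M)[nz]), con)
  invisible(path)
}
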