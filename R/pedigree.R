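#' Pedigree object
#'
#' A pedigree is a data.frame with integer columns `animal`, `sire`, `dam`
#' where 0 denotes an unknown parent and every parent appears before its
#' offspring (a topological order). This is the standard 3-column exchange
#' layout used by animal-breeding software.
#'
#' @param animal,sire,dam integer vectors of equal length.
#' @return a data.frame of class `pedigree`.
#' @export
pedigree <- function(animal, sire, dam) {
  ped <- data.frame(animal = as.integer(animal), sire = as.integer(sire),
                    dam = as.integer(dam))
  validate_pedigree(ped)
  class(ped) <- c("pedigree", class(ped))
  ped
}

validate_pedigree <- function(ped) {
  if (!all(c("animal", "sire", "dam") %in% names(ped)))
    stop("pedigree needs columns animal, sire, dam")
  if (anyDuplicated(ped$animal)) stop("duplicated animal ids in pedigree")
  if (any(ped$animal <= 0)) stop("animal ids must be positive integers")
  if (any(ped$animal == ped$sire | ped$animal == ped$dam))
    stop("an animal cannot be its own parent")
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- par != 0
    idx <- match(par[known], ped$animal)
    if (anyNA(idx))
      stop("unknown ", col, " id(s) referenced in pedigree")
    if (any(idx >= which(known)))
      stop("pedigree not sorted: every parent must precede its offspring")
  }
  invisible(ped)
}

#' Read / write a 3-column headerless pedigree CSV
#'
#' @param path file path; columns animal, sire, dam; 0 = unknown parent.
#' @return for `read_pedigree`, a [pedigree()].
#' @export
read_pedigree <- function(path) {
  x <- utils::read.csv(path, header = FALSE, comment.char = "#",
                       col.names = c("animal", "sire", "dam"))
  pedigree(x$animal, x$sire, x$dam)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @param header_comment optional comment line (e.g. seed provenance) written
#'   with a leading `#`.
#' @export
write_pedigree <- function(ped, path, header_comment = NULL) {
  validate_pedigree(ped)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(ped[c("animal", "sire", "dam")], con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Inbreeding coefficients
#'
#' Computes per-animal inbreeding coefficients F for a sorted pedigree using
#' the Meuwissen-Luo sparse-Cholesky recursion (exact, linear in the number
#' of ancestor links).
#'
#' @param ped a [pedigree()].
#' @return numeric vector of F, named by animal id.
#' @export
inbreeding <- function(ped) {
  validate_pedigree(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L) - 1L
  d <- match(ped$dam, ped$animal, nomatch = 0L) - 1L
  f <- ped_inbreeding(s, d)
  names(f) <- ped$animal
  f
}

#' Inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly by Henderson's rules, with inbreeding
#' accounted for through the Meuwissen-Luo coefficients, without ever
#' forming the dense A. The result is a sparse symmetric positive-definite
#' matrix ordered as the pedigree.
#'
#' @param ped a [pedigree()].
#' @return list with `Ainv` (a `dgCMatrix`), `F` (inbreeding coefficients)
#'   and `animal` (the id order of the rows).
#' @export
build_a_inverse <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L) - 1L
  d <- match(ped$dam, ped$animal, nomatch = 0L) - 1L
  f <- ped_inbreeding(s, d)
  tr <- ainverse_triplets(s, d, f)
  Ainv <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  structure(list(Ainv = Ainv, F = stats::setNames(f, ped$animal),
                 animal = ped$animal),
            class = "a_inverse")
}

#' Simulate a multi-generation pedigree with herd structure
#'
#' Builds a discrete-generation pedigree: `n_founders` unrelated founders
#' (half sires, half dams), then `n_generations` generations in which every
#' animal has both parents in the previous generation, so each final-
#' generation cow has `n_generations` complete ancestor generations. The
#' final generation holds the phenotyped cows (`n_herds * cows_per_herd`),
#' assigned at random to herd/date levels. Sires are sampled with strongly
#' unequal (Gamma-weighted) usage so half-sib families of a few up to many
#' tens of daughters arise and sires cut across herds, as in progeny-tested
#' dairy populations.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped` (a [pedigree()]), `cows` (ids of phenotyped
#'   cows), `herd` (herd/date id per cow, `1..n_herds`) and `sire_of_cow`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2) stop("need at least 2 founders (one sire, one dam)")
  if (!is.null(cfg$seed)) set.seed(seed_for(cfg$seed, "pedigree"))
  n_phen <- cfg$n_herds * cfg$cows_per_herd

  gen_sizes <- c(cfg$n_founders,
                 rep(cfg$n_founders, max(cfg$n_generations - 1, 0)),
                 if (cfg$n_generations >= 1) n_phen)
  total <- sum(gen_sizes)
  animal <- seq_len(total)
  sire <- integer(total)
  dam <- integer(total)
  sex <- integer(total) # 1 = male, 2 = female
  gen <- rep(seq_along(gen_sizes) - 1L, gen_sizes)

  # founders: alternate sexes
  idx0 <- which(gen == 0L)
  sex[idx0] <- rep_len(c(1L, 2L), length(idx0))
  if (sum(sex[idx0] == 1L) < 1 || sum(sex[idx0] == 2L) < 1)
    stop("impossible mating structure: need founders of both sexes")

  for (g in seq_len(cfg$n_generations)) {
    off <- which(gen == g)
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == 1L]
    females <- prev[sex[prev] == 2L]
    final <- g == cfg$n_generations
    n_sires <- if (final) min(cfg$n_active_sires, length(males))
               else max(2L, round(length(males) * 0.15))
    sires_used <- sample(males, n_sires)
    # heavily skewed usage -> family sizes spanning ~2..80 daughters
    w <- stats::rgamma(n_sires, shape = 0.8)
    sire[off] <- sample(sires_used, length(off), replace = TRUE, prob = w)
    # dams reused only a few times each
    dam[off] <- females[1L + (sample.int(length(off)) %% length(females))]
    sex[off] <- if (final) 2L else rep_len(c(1L, 2L), length(off))
  }

  ped <- pedigree(animal, sire, dam)
  if (cfg$n_generations >= 1) {
    cows <- which(gen == cfg$n_generations)
    herd <- rep(seq_len(cfg$n_herds), each = cfg$cows_per_herd)
    herd <- sample(herd) # random assignment: sires spread across herds
  } else {
    cows <- idx0
    herd <- rep_len(seq_len(cfg$n_herds), length(cows))
  }
  list(ped = ped, cows = as.integer(cows), herd = as.integer(herd),
       sire_of_cow = sire[cows])
}
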