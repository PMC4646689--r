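# Fixture pedigrees and independent oracles used across the tests.

# trio: child with two founder parents
trio_pedigree <- function() {
  pedigree(
    id = c("dad", "mum", "kid"),
    sire = c(NA, NA, "dad"),
    dam = c(NA, NA, "mum"),
    sex = c("male", "female", "female")
  )
}

# nuclear family: 2 parents, 3 children (2 F, 1 M)
nuclear_pedigree <- function() {
  pedigree(
    id = c("p1", "p2", "c1", "c2", "c3"),
    sire = c(NA, NA, "p1", "p1", "p1"),
    dam = c(NA, NA, "p2", "p2", "p2"),
    sex = c("male", "female", "female", "female", "male")
  )
}

# offspring of a full-sib mating (inbred, F = 0.25)
inbred_pedigree <- function() {
  pedigree(
    id = c("s", "d", "a", "b", "x"),
    sire = c(NA, NA, "s", "s", "a"),
    dam = c(NA, NA, "d", "d", "b"),
    sex = c("male", "female", "male", "female", "male")
  )
}

# three-generation, 20-member pedigree: grandparent couple, three adult
# children (two with married-in spouses and children of their own), one
# single; includes avuncular and first-cousin relationships.
fixture20_pedigree <- function() {
  ids <- c(
    "gf", "gm", # generation 0
    "a1", "a2", "a3", # their children
    "sp1", "sp2", # married-in spouses of a1 (F) and a2 (M)
    "b1", "b2", "b3", # children of a1 x sp1
    "b4", "b5", # children of a2 x sp2
    "sp3", # married-in spouse of b1
    "c1", "c2", # children of b1 x sp3
    "u1", "u2", # unrelated founder couple
    "v1", "v2", "v3" # their children
  )
  sire <- c(
    NA, NA,
    "gf", "gf", "gf",
    NA, NA,
    "sp1", "sp1", "sp1",
    "a2", "a2",
    NA,
    "sp3", "sp3",
    NA, NA,
    "u1", "u1", "u1"
  )
  dam <- c(
    NA, NA,
    "gm", "gm", "gm",
    NA, NA,
    "a1", "a1", "a1",
    "sp2", "sp2",
    NA,
    "b1", "b1",
    NA, NA,
    "u2", "u2", "u2"
  )
  sex <- c(
    "male", "female",
    "female", "male", "female",
    "male", "female",
    "female", "male", "female",
    "male", "female",
    "male",
    "female", "male",
    "male", "female",
    "female", "male", "female"
  )
  fam <- c(rep("famA", 15), rep("famB", 5))
  pedigree(ids, sire, dam, sex, fam)
}

# --- recursive-kinship oracle ----------------------------------------------
# Coancestry f(i, j) by the textbook recursion, memoised; A_oracle = 2 f.
kinship_oracle <- function(ped) {
  ind <- ped$ind
  n <- nrow(ind)
  s <- ind$sire_idx
  d <- ind$dam_idx
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(s[i], d[i]))
    } else if (i < j) {
      # j is never an ancestor of i in topological order
      0.5 * (f(i, s[j]) + f(i, d[j]))
    } else {
      0.5 * (f(j, s[i]) + f(j, d[i]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# --- exhaustive-pair dyad oracle -------------------------------------------
# Classifies every unordered pair through parent links alone; returns the
# set of sorted "i|j" keys for the requested class.
dyad_oracle <- function(ped, dyad_class) {
  ind <- ped$ind
  n <- nrow(ind)
  parents <- function(i) c(ind$sire_idx[i], ind$dam_idx[i])
  full_sibs <- function(i, j) {
    if (i == j) return(FALSE)
    p1 <- parents(i)
    p2 <- parents(j)
    all(p1 > 0) && all(p1 == p2)
  }
  is_parent <- function(i, j) any(parents(j) == i) || any(parents(i) == j)
  is_grandparent <- function(i, j) {
    gp <- function(a, b) {
      any(vapply(parents(b), function(p) p > 0 && any(parents(p) == a), logical(1)))
    }
    gp(i, j) || gp(j, i)
  }
  is_avuncular <- function(i, j) {
    av <- function(a, b) {
      any(vapply(parents(b), function(p) p > 0 && full_sibs(a, p), logical(1)))
    }
    av(i, j) || av(j, i)
  }
  is_cousin <- function(i, j) {
    if (full_sibs(i, j)) return(FALSE)
    pi_ <- parents(i)
    pj <- parents(j)
    any(outer(pi_, pj, Vectorize(function(a, b) {
      a > 0 && b > 0 && full_sibs(a, b)
    })))
  }
  test <- switch(dyad_class,
    full_siblings = full_sibs,
    full_sisters = function(i, j) {
      full_sibs(i, j) && all(ind$sex[c(i, j)] == "female")
    },
    full_brothers = function(i, j) {
      full_sibs(i, j) && all(ind$sex[c(i, j)] == "male")
    },
    opposite_sex_siblings = function(i, j) {
      full_sibs(i, j) && length(unique(ind$sex[c(i, j)])) == 2 &&
        !any(ind$sex[c(i, j)] == "unknown")
    },
    parent_child = is_parent,
    grandparent_grandchild = is_grandparent,
    avuncular = is_avuncular,
    first_cousins = is_cousin
  )
  keys <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (test(i, j)) {
        keys <- c(keys, paste(sort(c(ind$id[i], ind$id[j])), collapse = "|"))
      }
    }
  }
  sort(keys)
}

dyad_keys <- function(dy) {
  sort(vapply(
    seq_len(nrow(dy)),
    function(r) paste(sort(c(dy$id_i[r], dy$id_j[r])), collapse = "|"),
    character(1)
  ))
}

# bivariate-normal upper orthant probability P(Z1 > t, Z2 > t | rho) by
# one-dimensional numerical integration
orthant_upper <- function(t, rho) {
  stats::integrate(
    function(z) {
      stats::dnorm(z) * stats::pnorm((rho * z - t) / sqrt(1 - rho^2))
    },
    lower = t, upper = Inf, rel.tol = 1e-10
  )$value
}

# expected phi (0/1 Pearson) correlation for a liability threshold pair
expected_phi <- function(t, rho) {
  p <- stats::pnorm(-t) # P(Z > t)
  p11 <- orthant_upper(t, rho)
  (p11 - p^2) / (p * (1 - p))
}

# sib-pair families: 2 founder parents, `kids` children each, statuses from
# the liability simulator (c2 = 0 so the sib liability correlation is V_A/2
# over V_A + 1)
sibpair_data <- function(n_fam, h2, prevalence, seed, kids = 2) {
  cfg <- simulation_config(
    n_families = n_fam, seed = seed, h2_true = h2, c2_true = 0,
    target_prevalence = prevalence,
    template_probs = c(nuclear = 1, extended = 0),
    children_probs = c(numeric(kids - 1), 1),
    covariate_effects = NULL
  )
  ped <- simulate_pedigree(cfg)
  liab <- simulate_liabilities(ped, cfg)
  list(
    ped = ped, cfg = cfg,
    phen = data.frame(id = liab$id, status = liab$status),
    intercept = attr(liab, "intercept")
  )
}

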