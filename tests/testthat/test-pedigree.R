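test_that("reading a trio file yields a validated pedigree with founder parents", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# test trio",
    "kid dad mum F fam1",
    "dad 0 0 M fam1",
    "mum 0 0 F fam1"
  ), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(n_individuals(ped), 3)
  expect_setequal(ped$ind$id[ped$ind$founder], c("dad", "mum"))
  # parents precede offspring in the stored order
  expect_lt(match("dad", ped$ind$id), match("kid", ped$ind$id))

  # comma-separated variant reads identically
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kid,dad,mum,F,fam1", "dad,0,0,M,fam1", "mum,0,0,F,fam1"), f2)
  expect_equal(read_pedigree(f2)$ind, ped$ind)
})

test_that("parentage cycles and sex-inconsistent parents are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B 0 M", "B C 0 M", "C A 0 M"), f)
  expect_error(read_pedigree(f), "cycle")

  # an id used as a father also appearing as someone's mother
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("x p 0 M", "y 0 p F", "p 0 0 M"), f2)
  expect_error(read_pedigree(f2), "both as sire and dam")

  # listed sex contradicts parental role
  expect_error(
    pedigree(c("p", "k"), sire = c(NA, "p"), dam = NA, sex = c("female", "male")),
    "sex inconsistent"
  )
  expect_error(
    pedigree("a", sire = "a", dam = NA, sex = "male"),
    "own parent"
  )
})

test_that("phantom parents are auto-inserted as founders with role-inferred sex", {
  expect_message(
    ped <- pedigree(c("kid"), sire = "dad", dam = "mum", sex = "female"),
    "inserted as founders"
  )
  expect_equal(n_individuals(ped), 3)
  expect_equal(ped$n_phantom, 2)
  expect_equal(ped$ind$sex[ped$ind$id == "dad"], "male")
  expect_equal(ped$ind$sex[ped$ind$id == "mum"], "female")
})

test_that("A matrix reproduces textbook additive relationships", {
  A <- as.matrix(additive_relationship_matrix(nuclear_pedigree()))
  expect_equal(A["p1", "c1"], 0.5) # parent-offspring
  expect_equal(A["c1", "c2"], 0.5) # full siblings
  expect_equal(A["p1", "p2"], 0) # unrelated founders
  expect_equal(unname(diag(A)), rep(1, 5))

  # first cousins share 0.125
  A20 <- as.matrix(additive_relationship_matrix(fixture20_pedigree()))
  expect_equal(A20["b1", "b4"], 0.125) # children of full sibs a1, a2

  # offspring of a full-sib mating: F = 0.25, diagonal 1.25
  Ai <- as.matrix(additive_relationship_matrix(inbred_pedigree()))
  expect_equal(Ai["x", "x"], 1.25)
  expect_equal(inbreeding(inbred_pedigree()), c(0, 0, 0, 0, 0.25))
})

test_that("A equals twice the recursive-kinship oracle and is PSD on all fixtures", {
  for (ped in list(
    trio_pedigree(), nuclear_pedigree(), inbred_pedigree(),
    fixture20_pedigree()
  )) {
    A <- as.matrix(additive_relationship_matrix(ped))
    expect_lt(max(abs(A - kinship_oracle(ped))), 1e-12)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("sparse A-inverse agrees with the dense inverse", {
  for (ped in list(nuclear_pedigree(), inbred_pedigree(), fixture20_pedigree())) {
    A <- as.matrix(additive_relationship_matrix(ped))
    expect_lt(max(abs(as.matrix(a_inverse(ped)) - solve(A))), 1e-10)
  }
})

test_that("pairwise relationships are invariant to record permutation", {
  ped <- fixture20_pedigree()
  A <- as.matrix(additive_relationship_matrix(ped))
  ind <- ped$ind
  set.seed(4)
  perm <- sample(nrow(ind))
  ped2 <- pedigree(ind$id[perm], ind$sire[perm], ind$dam[perm], ind$sex[perm],
    ind$family_group[perm])
  A2 <- as.matrix(additive_relationship_matrix(ped2))
  expect_equal(A2[rownames(A), colnames(A)], A)
})

test_that("dyad extraction matches combinatorics and the exhaustive-pair oracle", {
  ped <- nuclear_pedigree() # 3 children: 2 F, 1 M
  expect_equal(nrow(extract_dyads(ped, "full_siblings")), 3)
  expect_equal(nrow(extract_dyads(ped, "full_sisters")), 1)
  expect_equal(nrow(extract_dyads(ped, "opposite_sex_siblings")), 2)
  expect_equal(nrow(extract_dyads(ped, "parent_child")), 6)
  expect_error(extract_dyads(ped, "second_cousins"), "arg")

  # two unrelated trios share no cousins
  two_trios <- pedigree(
    id = c("a", "b", "c", "x", "y", "z"),
    sire = c(NA, NA, "a", NA, NA, "x"),
    dam = c(NA, NA, "b", NA, NA, "y"),
    sex = c("male", "female", "male", "male", "female", "female")
  )
  expect_equal(nrow(extract_dyads(two_trios, "first_cousins")), 0)

  # every class against brute-force classification on the 20-member fixture
  ped20 <- fixture20_pedigree()
  for (cl in dyad_classes()) {
    expect_equal(dyad_keys(extract_dyads(ped20, cl)), dyad_oracle(ped20, cl),
      info = cl
    )
  }
})

test_that("each dyad pair is stored once regardless of orientation", {
  dy <- extract_dyads(fixture20_pedigree(), "full_siblings")
  keys <- dyad_keys(dy)
  expect_equal(anyDuplicated(keys), 0)
})

test_that("informative-relationship counting follows the either-affected rule", {
  ped <- trio_pedigree()
  phen <- data.frame(id = c("dad", "mum", "kid"), status = c(0, 0, 1))
  tab <- count_informative_relationships(ped, phen)
  get <- function(cl) tab$n[tab$relationship == cl]
  expect_equal(get("mother-child"), 1)
  expect_equal(get("father-child"), 1)
  expect_equal(get("total"), 2)

  # all unaffected: nothing informative under the default rule
  phen0 <- data.frame(id = c("dad", "mum", "kid"), status = c(0, 0, 0))
  expect_true(all(count_informative_relationships(ped, phen0)$n == 0))
  # ... but both-nonmissing counts the complete pairs
  tab2 <- count_informative_relationships(ped, phen0, rule = "both_nonmissing")
  expect_equal(tab2$n[tab2$relationship == "total"], 2)
})

test_that("informative counts equal the exhaustive-pair oracle on the fixture", {
  ped <- fixture20_pedigree()
  set.seed(9)
  ids <- ped$ind$id
  status <- integer(20)
  status[sample(20, 5)] <- 1L
  status[sample(which(status == 0), 2)] <- NA_integer_
  phen <- data.frame(id = ids, status = status)
  tab <- count_informative_relationships(ped, phen)

  ind <- ped$ind
  st <- status[match(ind$id, ids)]
  count_class <- function(pairs) {
    if (!nrow(pairs)) return(0L)
    s1 <- st[pairs[, 1]]
    s2 <- st[pairs[, 2]]
    sum(!is.na(s1) & !is.na(s2) & (s1 == 1 | s2 == 1))
  }
  # brute-force mother-child pairs
  mc <- 0L
  fc <- 0L
  for (i in seq_len(20)) {
    if (ind$dam_idx[i] > 0) mc <- mc + count_class(cbind(ind$dam_idx[i], i))
    if (ind$sire_idx[i] > 0) fc <- fc + count_class(cbind(ind$sire_idx[i], i))
  }
  expect_equal(tab$n[tab$relationship == "mother-child"], mc)
  expect_equal(tab$n[tab$relationship == "father-child"], fc)
  expect_equal(
    tab$n[tab$relationship == "total"],
    sum(tab$n[tab$relationship != "total"])
  )
})

test_that("pedigree and relationship-matrix writers round-trip", {
  ped <- fixture20_pedigree()
  f <- withr::local_tempfile(fileext = ".txt")
  write_pedigree(ped, f)
  ped2 <- read_pedigree(f)
  expect_equal(ped2$ind, ped$ind)

  A <- additive_relationship_matrix(ped)
  fs <- withr::local_tempfile(fileext = ".txt")
  write_relationship_matrix(A, fs)
  tab <- read.table(fs, header = TRUE, colClasses = c("character", "character", "numeric"))
  back <- matrix(0, 20, 20, dimnames = dimnames(A))
  for (r in seq_len(nrow(tab))) {
    back[tab$id_i[r], tab$id_j[r]] <- tab$a_ij[r]
    back[tab$id_j[r], tab$id_i[r]] <- tab$a_ij[r]
  }
  expect_equal(back, as.matrix(A), ignore_attr = TRUE)

  fd <- withr::local_tempfile(fileext = ".csv")
  write_relationship_matrix(A, fd, dense = TRUE)
  dense <- as.matrix(read.csv(fd, row.names = 1, check.names = FALSE))
  expect_equal(dense, as.matrix(A), ignore_attr = TRUE)
  expect_error(
    write_relationship_matrix(A, fd, dense = TRUE, dense_limit = 10),
    "dense output limited"
  )
})
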