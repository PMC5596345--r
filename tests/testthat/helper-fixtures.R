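# small pedigrees built in code

make_ped <- function(id, father = NA, mother = NA, sex = "female",
                     age = 30, household = NA, city = "city1",
                     moved_out = NA, childhood_household = NA) {
  d <- data.frame(id = id,
                  father = rep_len(as.character(father), length(id)),
                  mother = rep_len(as.character(mother), length(id)),
                  sex = rep_len(sex, length(id)),
                  age = rep_len(age, length(id)),
                  household = rep_len(as.character(household), length(id)),
                  city = rep_len(city, length(id)),
                  moved_out = rep_len(moved_out, length(id)),
                  childhood_household = rep_len(as.character(childhood_household),
                                                length(id)),
                  stringsAsFactors = FALSE)
  class(d) <- c("fam_pedigree", "data.frame")
  d
}

# grandparents -> two sibs (P1, P2) married to founders -> first cousins
# (X, Y) -> Z, a child of first-cousin parents (inbred)
ped_cousin_marriage <- function() {
  rbind(
    make_ped("G1", sex = "male", age = 90, household = "H0"),
    make_ped("G2", sex = "female", age = 88, household = "H0"),
    make_ped("P1", "G1", "G2", sex = "male", age = 60, household = "H1"),
    make_ped("P2", "G1", "G2", sex = "female", age = 58, household = "H2"),
    make_ped("S1", sex = "female", age = 59, household = "H1"),
    make_ped("S2", sex = "male", age = 60, household = "H2"),
    make_ped("X", "P1", "S1", sex = "male", age = 30, household = "H3"),
    make_ped("Y", "S2", "P2", sex = "female", age = 29, household = "H3"),
    make_ped("Z", "X", "Y", sex = "female", age = 5, household = "H3")
  ) -> d
  class(d) <- c("fam_pedigree", "data.frame")
  d
}

# K unrelated founder couples, two children each: K independent sib pairs
ped_sib_pairs <- function(K) {
  rows <- lapply(seq_len(K), function(k) {
    fa <- sprintf("F%04d", k); mo <- sprintf("M%04d", k)
    rbind(make_ped(fa, sex = "male"), make_ped(mo, sex = "female"),
          make_ped(sprintf("C%04da", k), fa, mo),
          make_ped(sprintf("C%04db", k), fa, mo))
  })
  d <- do.call(rbind, rows)
  class(d) <- c("fam_pedigree", "data.frame")
  d
}

# tiny phylotype table with two genera and planted counts
toy_table <- function() {
  counts <- rbind(s1 = c(6L, 2L, 2L, 0L),
                  s2 = c(3L, 3L, 0L, 4L),
                  s3 = c(0L, 0L, 5L, 5L))
  colnames(counts) <- c("pA1", "pA2", "pB1", "pB2")
  tax <- data.frame(phylotype = colnames(counts),
                    genus = c("Alpha", "Alpha", "Beta", "Beta"),
                    phylum = "Firmicutes", stringsAsFactors = FALSE)
  phylotype_table(counts, tax)
}
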