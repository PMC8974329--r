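# Small pedigrees and tables built in code for the tests.

ped_trio <- function() {
  pedigree(data.frame(fid = "1", id = c("F", "M", "C"),
                      father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
                      sex = c(1, 2, 1)))
}

ped_sibs <- function(n_sibs = 3) {
  ids <- paste0("S", seq_len(n_sibs))
  pedigree(data.frame(fid = "1", id = c("F", "M", ids),
                      father = c(NA, NA, rep("F", n_sibs)),
                      mother = c(NA, NA, rep("M", n_sibs)),
                      sex = c(1, 2, rep_len(c(1, 2), n_sibs))))
}

# half sibs: father F with mothers M1, M2
ped_halfsibs <- function() {
  pedigree(data.frame(fid = "1", id = c("F", "M1", "M2", "A", "B"),
                      father = c(NA, NA, NA, "F", "F"),
                      mother = c(NA, NA, NA, "M1", "M2"),
                      sex = c(1, 2, 2, 1, 1)))
}

# three generations: grandparents, two children w/ spouses, grandchildren
ped_threegen <- function() {
  pedigree(data.frame(
    fid = "1",
    id     = c("GF", "GM", "A", "B", "As", "Bs", "C", "D", "E"),
    father = c(NA, NA, "GF", "GF", NA, NA, "A", "A", "B"),
    mother = c(NA, NA, "GM", "GM", NA, NA, "As", "As", "Bs"),
    sex    = c(1, 2, 1, 1, 2, 2, 1, 2, 1)))
}

# random multi-generation pedigree with at most max_members members
random_pedigree <- function(seed, max_members = 30) {
  set.seed(seed)
  rows <- data.frame(fid = "R", id = c("F0", "M0"),
                     father = c(NA, NA), mother = c(NA, NA),
                     sex = c("male", "female"), stringsAsFactors = FALSE)
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; paste0("I", nid) }
  add_children <- function(fa, mo, gen) {
    kids <- character(0)
    for (k in seq_len(sample(1:4, 1))) {
      if (nrow(rows) >= max_members - 1) break
      id <- new_id()
      rows <<- rbind(rows, data.frame(fid = "R", id = id, father = fa,
                                      mother = mo,
                                      sex = sample(c("male", "female"), 1),
                                      stringsAsFactors = FALSE))
      kids <- c(kids, id)
    }
    if (gen < 3) {
      for (id in kids) {
        if (nrow(rows) >= max_members - 2) break
        if (runif(1) < 0.6) {
          sx <- rows$sex[rows$id == id]
          sp <- new_id()
          rows <<- rbind(rows, data.frame(fid = "R", id = sp, father = NA,
                                          mother = NA,
                                          sex = if (sx == "male") "female"
                                                else "male",
                                          stringsAsFactors = FALSE))
          fa2 <- if (sx == "male") id else sp
          mo2 <- if (sx == "male") sp else id
          add_children(fa2, mo2, gen + 1)
        }
      }
    }
  }
  add_children("F0", "M0", 1)
  pedigree(rows)
}

gomp_table <- function(a = 1e-4, b = 0.085, max_age = 110) {
  make_gompertz_table(a, b, sex = "female", cohort_start = 1880,
                      cohort_end = 1960, max_age = max_age)
}

two_sex_table <- function() make_gompertz_table2(cohort_start = 1870,
                                                 cohort_end = 1990)

# demo-style single family (sibship + spouses + offspring), ids prefixed
demo_family <- function(sibship = 3, offspring = 2, fid = "X") {
  fam <- famlong:::raredrop_family(fid, sibship, offspring)
  fam$id <- paste(fid, fam$id, sep = ":")
  fam$father <- ifelse(is.na(fam$father), NA,
                       paste(fid, fam$father, sep = ":"))
  fam$mother <- ifelse(is.na(fam$mother), NA,
                       paste(fid, fam$mother, sep = ":"))
  pedigree(fam)
}
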