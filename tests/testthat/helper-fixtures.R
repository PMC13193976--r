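# In-code text fixtures for the bibliographic parsers.

wos_fixture <- function(rows = NULL) {
  header <- paste(c("UT", "TI", "AB", "DE", "ID", "PY", "TC", "SO", "C1"),
                  collapse = "\t")
  default_rows <- c(
    paste(c("WOS:000001", "Bone loss in aging", "An abstract.",
            "Osteoporosis; Bone Loss", "Aging; Fracture", "2020", "5",
            "Bone", "Univ A, Guangzhou, Peoples R China."), collapse = "\t"),
    paste(c("WOS:000002", "Sclerostin and bone formation", "",
            "Sclerostin; Bone Formation", "", "2021", "12", "Bone",
            "Univ B, Boston, MA, USA.; Univ C, Oxford, England."),
          collapse = "\t"),
    paste(c("WOS:000003", "A broken year", "", "Osteocalcin", "", "n/a",
            "3", "Bone", ""), collapse = "\t"))
  paste(c(header, rows %||% default_rows), collapse = "\n")
}

nbib_fixture <- function() {
  paste(c(
    "PMID- 100001",
    "TI  - Gut microbiota and bone loss",
    "AB  - Abstract text",
    "DP  - 2021 Mar",
    "OT  - osteoporosis",
    "OT  - gut",
    "      microbiota",
    "MH  - Biomarkers/blood",
    "MH  - Bone Density",
    "SO  - J Bone Res",
    "",
    "TI  - Record without a PMID",
    "DP  - 2020",
    "OT  - orphan keyword",
    "",
    "PMID- 100002",
    "TI  - Sclerostin and bone formation",
    "DP  - 2021 Jan",
    "OT  - sclerostin",
    "MH  - Osteogenesis"), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
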