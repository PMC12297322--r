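## Valid population selectors for the feedback arguments c1, c2, c3.
.selectors <- c("Q", "A", "Q+A", "T0", "sumT", "N")

.selector_value <- function(state, sel) {
  n <- length(state) - 4L
  switch(sel,
         "Q" = state[["Q"]],
         "A" = state[["A"]],
         "Q+A" = state[["Q"]] + state[["A"]],
         "T0" = state[["T0"]],
         "sumT" = sum(state[paste0("T", 0:n)]),
         "N" = state[["N"]],
         stop(sprintf("unknown population selector '%s'; valid: %s",
                      sel, paste(.selectors, collapse = ", "))))
}

.make_scenario <- function(name, c1, c2, c3, extended_r = FALSE) {
  structure(list(name = name, c1 = c1, c2 = c2, c3 = c3,
                 uses_r1 = extended_r),
            class = "lineage_scenario")
}

## The registry. The five canonical wild-type scenarios, their extended-
## numerator knockout counterparts (marked "r*"), and the Delta-Notch-Wnt
## scenario r(Q, Q+A), b(Q) obtained by a quasi-steady-state reduction of
## Delta-ligand kinetics combined with Wnt-regulated self-renewal.
.scenario_defs <- list(
  list("r(Q,A),b(A)",      "Q",   "A",   "A"),
  list("r(Q,A),b(Q)",      "Q",   "A",   "Q"),
  list("r(Q,A),b(N)",      "Q",   "A",   "N"),
  list("r(Q+A),b(Q+A)",    "Q+A", "Q+A", "Q+A"),
  list("r(Q,T0),b(N)",     "Q",   "T0",  "N"),
  list("r(Q,Q+A),b(Q)",    "Q",   "Q+A", "Q")
)

.scenario_registry <- local({
  reg <- list()
  for (d in .scenario_defs) {
    reg[[d[[1]]]] <- .make_scenario(d[[1]], d[[2]], d[[3]], d[[4]], FALSE)
    ko <- sub("^r\\(", "r*(", d[[1]])
    ko <- sub("^r\\*?\\(Q\\+A\\)", "r*(Q+A)", ko)
    reg[[ko]] <- .make_scenario(ko, d[[2]], d[[3]], d[[4]], TRUE)
  }
  reg
})

## Accept the long form r(c,c) for the single-argument shorthand r(c).
.normalize_scenario_name <- function(name) {
  name <- gsub(" ", "", name)
  m <- regmatches(name, regexec("^(r\\*?)\\(([^,()]+),([^,()]+)\\)(,b\\(.+\\))$",
                                name))[[1]]
  if (length(m) && m[3] == m[4]) name <- paste0(m[2], "(", m[3], ")", m[5])
  name
}

#' Feedback scenarios: which populations regulate activation and self-renewal
#'
#' A scenario names the subpopulations inserted into the feedback functions:
#' `c1` promotes activation (numerator of `r`), `c2` inhibits activation
#' (denominator of `r`) and `c3` inhibits self-renewal (denominator of `b`).
#' Scenario names follow the field's shorthand, e.g. `"r(Q,A),b(Q)"` means
#' qNSCs promote and aNSCs inhibit activation while qNSCs inhibit
#' self-renewal; the single-argument form `r(c)` abbreviates `r(c, c)`.
#' Names prefixed `r*` use the extended activation numerator
#' \eqn{r_1 + r_0 c_1} (the knockout form, where `r1` is a free parameter);
#' the plain form fixes `r1 = 0`.
#'
#' @param name a registry name, see [list_scenarios()].
#' @return An object of class `"lineage_scenario"` with fields `name`, `c1`,
#'   `c2`, `c3` and `uses_r1`.
#' @examples
#' scenario("r(Q,A),b(Q)")
#' scenario("r(Q+A,Q+A),b(Q+A)")  # long form of "r(Q+A),b(Q+A)"
#' @export
scenario <- function(name) {
  key <- .normalize_scenario_name(name)
  sc <- .scenario_registry[[key]]
  if (is.null(sc))
    stop(sprintf("unknown scenario '%s'; valid names are:\n  %s",
                 name, paste(names(.scenario_registry), collapse = "\n  ")))
  sc
}

#' @rdname scenario
#' @param wild_type_only if `TRUE`, only the five canonical wild-type
#'   scenarios (with `r1 = 0`).
#' @export
list_scenarios <- function(wild_type_only = FALSE) {
  nm <- names(.scenario_registry)
  if (wild_type_only)
    nm <- setdiff(grep("^r\\*", nm, value = TRUE, invert = TRUE),
                  "r(Q,Q+A),b(Q)")
  nm
}

#' @export
print.lineage_scenario <- function(x, ...) {
  num <- if (x$uses_r1) paste0("(r1 + r0 ", x$c1, ")") else paste0("r0 ", x$c1)
  cat(sprintf("Scenario %s\n  r = %s / (K + %s)\n  b = b0 / (1 + beta %s)\n",
              x$name, num, x$c2, x$c3))
  invisible(x)
}
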