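# Fixture builders and independent brute-force oracles used across tests.

rec <- function(adm, dis, person = "P1", era = "ICD10", main = "T24.1",
                n2 = NA_character_, n3 = NA_character_, e = NA_character_,
                provider = "UNIVERSITY", specialty = "OTHER", ltc = FALSE) {
  data.frame(person_id = person,
             admission_date = as.Date(adm), discharge_date = as.Date(dis),
             provider_type = provider, specialty = specialty,
             long_term_care = ltc, era = era,
             main_ncode = main, ncode2 = n2, ncode3 = n3, ecode = e,
             stringsAsFactors = FALSE)
}

regs <- function(...) do.call(rbind, list(...))

# brute-force episode oracle: transitive closure of pairwise overlap of the
# record intervals extended by the gap tolerance at the discharge end
oracle_episode_groups <- function(df, gap = 2) {
  groups <- integer(nrow(df))
  next_id <- 0L
  for (p in unique(df$person_id)) {
    i <- which(df$person_id == p)
    adm <- as.numeric(as.Date(df$admission_date[i]))
    dis <- as.numeric(as.Date(df$discharge_date[i]))
    g <- seq_along(i)
    repeat {
      changed <- FALSE
      for (a in seq_along(i)) for (b in seq_along(i)) {
        if (g[a] != g[b] &&
            adm[b] <= dis[a] + gap && adm[a] <= dis[b] + gap) {
          g[g == g[b]] <- g[a]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    groups[i] <- next_id + match(g, unique(g))
    next_id <- next_id + length(unique(g))
  }
  groups
}

# brute-force bed-day oracle: enumerate the days covered by [adm, dis)
oracle_bed_days <- function(adm, dis) {
  if (length(adm) == 0L) return(0)
  adm <- as.numeric(as.Date(adm)); dis <- as.numeric(as.Date(dis))
  days <- unique(unlist(Map(function(a, d) if (d > a) a:(d - 1) else NULL,
                            adm, dis)))
  max(length(days), 1)
}

# random one-person histories for the episode-construction equivalence suite
random_history <- function(person, n_max = 8) {
  n <- sample.int(n_max, 1)
  adm <- as.Date("2000-01-01") + sort(sample.int(400, n, replace = TRUE))
  stay <- sample(0:10, n, replace = TRUE)
  rec(adm, adm + stay, person = person)
}
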