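# Internal constants and helpers shared across modules.

# Chronic conditions tracked as absorbing flags on every simulated person.
DISEASES <- c("diabetes", "hypertension", "stroke", "cancer",
              "heart_disease", "lung_disease", "dementia")

# CVD mortality is all-cause death of persons with a *lagged* diagnosis of
# heart disease or stroke; the prevention channel additionally acts on
# hypertension incidence.
CVD_MORTALITY_DISEASES <- c("heart_disease", "stroke")
CVD_INCIDENCE_DISEASES <- c("heart_disease", "stroke", "hypertension")

COST_CATEGORIES <- c("hospital_nights", "specialist_visits", "generalist_visits")

MAX_AGE <- 110L
MIN_AGE <- 30L

# Covariates a transition or cost model may reference.  All are lagged
# (start-of-cycle) person fields or fixed transforms of them, so the
# within-cycle dependency graph is acyclic by construction.
COVARIATE_VOCAB <- c("age_c", "age_c2", "male", "education2", "education3",
                     "immigrant", "smoker", "obese", "activity_limited",
                     "cognitively_impaired", "in_ltc", DISEASES)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic sub-stream seeds: offsets keep replication counts from
# perturbing unrelated streams.  Exact in double arithmetic (< 2^53) and
# the result stays below 2^31 - 1.
substream <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 2147483629) * 1000003 + as.numeric(offset) * 7919
  as.integer(s %% 2147483629) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 5-year age bands 30-34, ..., 105-110 (last band absorbs age 110).
AGE_BAND_BREAKS <- seq(30L, 105L, by = 5L)
AGE_BAND_LABELS <- paste0(AGE_BAND_BREAKS, "-", AGE_BAND_BREAKS + 4L)
N_AGE_BANDS <- length(AGE_BAND_BREAKS)

age_band_index <- function(age) {
  pmin(((age - MIN_AGE) %/% 5L) + 1L, N_AGE_BANDS)
}

# Weighted sum by band returning a full-length vector (zeros where empty).
band_sum <- function(age, w) {
  idx <- age_band_index(age)
  out <- numeric(N_AGE_BANDS)
  if (length(idx)) {
    s <- tapply(w, factor(idx, levels = seq_len(N_AGE_BANDS)), sum)
    out <- as.numeric(ifelse(is.na(s), 0, s))
  }
  names(out) <- AGE_BAND_LABELS
  out
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
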