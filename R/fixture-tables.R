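# Embedded marginal-count tables the reference corpus reproduces exactly.
# These are the fixture's ground truth; reference_corpus() is constructed so
# the pipeline's outputs match them cell by cell.

# ads / food ads / analyzed hours, by program rating x study week
fixture_rating_week <- function() {
  tibble::tribble(
    ~program_rating, ~week_id, ~n_total, ~n_food, ~hours,
    "C",  1L,   22L,  11L,  2.93,
    "C",  2L,   19L,  10L,  2.07,
    "C",  3L,   11L,   6L,  3.08,
    "C",  4L,   29L,   8L,  2.90,
    "G",  1L,  442L, 171L, 24.87,
    "G",  2L,  808L, 242L, 37.45,
    "G",  3L,  651L, 227L, 29.64,
    "G",  4L,  652L, 178L, 41.22,
    "PG", 1L,  270L,  54L, 15.10,
    "PG", 2L,  582L, 186L, 24.57,
    "PG", 3L,  653L, 231L, 26.73,
    "PG", 4L,  371L,  69L, 15.90
  )
}

# categorized food ads by category x rating (column sums 36 / 845 / 555;
# these exceed the rating food-ad totals 35 / 818 / 540 by 1 / 27 / 15 -- a
# known inconsistency of the source tabulation, carried in fixture metadata)
fixture_category_rating <- function() {
  tibble::tribble(
    ~category_id, ~C, ~G, ~PG,
    "1",  12L, 140L,  56L,
    "2",   6L,  56L,  42L,
    "3a",  0L,   7L,   4L,
    "3c",  5L,  28L,  19L,
    "3d",  0L,  31L,  11L,
    "3e",  4L,  37L,  18L,
    "5",   0L,   1L,   3L,
    "6",   0L, 142L, 113L,
    "8",   0L,  11L,  17L,
    "9",   9L,  43L,  19L,
    "10",  0L,  19L,   0L,
    "12",  0L,   2L,   0L,
    "13",  0L,  57L,  74L,
    "14",  0L,  18L,  22L,
    "18",  0L,  31L,  14L,
    "19",  0L, 134L,  94L,
    "20",  0L,  88L,  49L
  )
}

# permitted counts under the 18-category basis, by rating
fixture_permitted <- function() {
  tibble::tribble(
    ~program_rating, ~n_food_emr18, ~n_permitted,
    "C",  35L, 0L,
    "G",  596L, 88L,
    "PG", 397L, 80L
  )
}

# health/nutrition-claim and disclaimer counts among food ads, by rating
fixture_claims <- function() {
  tibble::tribble(
    ~program_rating, ~n_claims, ~n_disclaimers,
    "C",   5L,  1L,
    "G",  157L, 31L,
    "PG",  87L, 22L
  )
}

# analyzed hours by channel x week (whole hours; used only to apportion the
# fractional rating x week hours across channels)
fixture_channel_week_hours <- function() {
  tibble::tribble(
    ~channel, ~week_id, ~hours,
    "A", 1L, 25, "A", 2L, 29, "A", 3L, 24, "A", 4L, 24,
    "B", 1L, 18, "B", 2L, 14, "B", 3L, 17, "B", 4L, 16,
    "C", 1L,  0, "C", 2L, 22, "C", 3L, 19, "C", 4L, 18
  )
}
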