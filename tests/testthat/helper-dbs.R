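# In-code fixtures: tiny databases built programmatically for the unit tests.

tiny_records <- function(n = 3, year_label = "2017", code_prefix = "C") {
  if (n == 0) return(tiny_records(1, year_label, code_prefix)[0, ])
  data.frame(
    product_code = paste0(code_prefix, seq_len(n)),
    retailer_id = "RA",
    brand = "B", brand_type = "multinational",
    tra_category = "C",
    container_size = 500, container_unit = "g",
    serving_size = 100, serving_unit = "g",
    price = 5,
    energy_kcal = 100, fat_g = 3, satfat_g = 1, carb_g = 15, sugars_g = 4,
    fibre_g = 2, protein_g = 4, sodium_mg = 80, calcium_mg = 50,
    fvnl_percent = 0,
    year_label = year_label,
    stringsAsFactors = FALSE)
}

tiny_db <- function(n = 3, year_label = "2017", ...) {
  food_db(tiny_records(n, year_label, ...), year_label)
}

# a matched-pairs object from two databases that differ only where stated
tiny_pairs <- function(n = 3, mutate_y2 = identity) {
  r2 <- tiny_records(n, "2020")
  r2 <- mutate_y2(r2)
  match_products(tiny_db(n, "2017"), food_db(r2, "2020"))
}

stub_steps <- function() matrix(c(335, 670, 1, 2), ncol = 2)
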