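Package: biosyndist
Title: Biosynthetically Informed Distances Between Secondary Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares secondary metabolite profiles (e.g. floral volatile
    bouquets) while accounting for the biosynthetic origin of the compounds.
    Compound-level Soerensen dissimilarities are computed from shared
    biosynthetic enzymes (or chemical classes), clustered into a biosynthesis
    dendrogram, and sample-level distances are obtained as weighted
    generalized UniFrac distances over that tree. Also provides the weighted
    fusion of class-based distances with Bray-Curtis dissimilarities, a
    Mantel-based scan for the optimal fusion weight, Mantel tests, NMDS
    ordination with a factor goodness-of-fit, and seeded synthetic data
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
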