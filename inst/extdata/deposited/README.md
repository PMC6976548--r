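# Deposited case-study datasets (not redistributed)

The four case-study datasets (flat, increasing, decreasing and unimodal
hazards; n = 400 each, administrative censoring at 1 year) are third-party
research data deposited at the University of Sheffield figshare archive
(`https://figshare.shef.ac.uk/articles/Data_Rda/9751907/2`, `Data.Rda`).
They are not shipped with this package.  To run the deposited-data
replication checks, fetch the deposit once and convert it to CSV here:

```r
load("Data.Rda")   # objects: one data frame per dataset, columns time/event
# inspect ls() for the object names, then for each dataset:
hazext::write_dataset(
  hazext::survival_data(<obj>$time, <obj>$event),
  file.path(system.file("extdata", "deposited", package = "hazext"),
            "dataset_<kind>.csv"))
```

yielding `dataset_flat.csv`, `dataset_increasing.csv`,
`dataset_decreasing.csv`, `dataset_unimodal.csv` (two columns: `time`,
`event`).  Without these files, the synthetic generator ships statistically
equivalent — but not identical — realisations of the same designs.
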