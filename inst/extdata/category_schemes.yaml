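# Total-score categorization schemes. Bins are inclusive ranges of the
# total score; the highest bin is the reference for hazard-ratio
# reporting. five_year_rate / ci are the published survival summaries
# attached to each bin, used by score_patient() when no cohort is
# supplied.
category1:
  bins:
    - {lo: 32, hi: 36, five_year_rate: 3.6,  ci: [0.0, 10.5]}
    - {lo: 37, hi: 38, five_year_rate: 23.2, ci: [4.3, 42.2]}
    - {lo: 39, hi: 41, five_year_rate: 19.0, ci: [9.8, 28.1]}
    - {lo: 42, hi: 44, five_year_rate: 29.0, ci: [20.1, 37.9]}
    - {lo: 45, hi: 47, five_year_rate: 50.5, ci: [42.7, 58.3]}
    - {lo: 48, hi: 49, five_year_rate: 72.1, ci: [65.6, 78.6]}
    - {lo: 50, hi: 52, five_year_rate: 84.7, ci: [79.6, 89.8]}
category2:
  bins:
    - {lo: 32, hi: 35, five_year_rate: 5.3,  ci: [0.0, 15.4]}
    - {lo: 36, hi: 38, five_year_rate: 15.2, ci: [1.7, 28.7]}
    - {lo: 39, hi: 41, five_year_rate: 19.0, ci: [9.8, 28.1]}
    - {lo: 42, hi: 44, five_year_rate: 29.0, ci: [20.1, 37.9]}
    - {lo: 45, hi: 47, five_year_rate: 50.5, ci: [42.7, 58.3]}
    - {lo: 48, hi: 50, five_year_rate: 75.7, ci: [71.0, 80.5]}
    - {lo: 51, hi: 52, five_year_rate: 94.1, ci: [89.0, 99.2]}
category3:
  bins:
    - {lo: 32, hi: 35, five_year_rate: 5.3,  ci: [0.0, 15.4]}
    - {lo: 36, hi: 39, five_year_rate: 21.0, ci: [9.7, 32.3]}
    - {lo: 40, hi: 43, five_year_rate: 18.6, ci: [10.7, 26.4]}
    - {lo: 44, hi: 47, five_year_rate: 48.3, ci: [41.5, 55.2]}
    - {lo: 48, hi: 50, five_year_rate: 75.7, ci: [71.0, 80.5]}
    - {lo: 51, hi: 52, five_year_rate: 94.1, ci: [89.0, 99.2]}
category4:
  bins:
    - {lo: 32, hi: 37, five_year_rate: 8.3,  ci: [0.0, 17.1]}
    - {lo: 38, hi: 43, five_year_rate: 20.0, ci: [13.0, 27.0]}
    - {lo: 44, hi: 47, five_year_rate: 48.3, ci: [41.5, 55.2]}
    - {lo: 48, hi: 49, five_year_rate: 72.1, ci: [65.6, 78.6]}
    - {lo: 50, hi: 52, five_year_rate: 84.7, ci: [79.6, 89.8]}
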