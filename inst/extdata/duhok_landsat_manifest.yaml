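# Landsat scene catalog for the Duhok winter-crop analysis (Path 170 Row 034).
# 47 scenes across four epochs; dates are year and Julian day of year.
# 44 scenes are LEDAPS surface-reflectance products; three (marked
# digital_number) were raw and are corrected in-package with DOS3.
# segmentation: true marks the scene used for per-period segmentation.
periods:
  - id: A
    label: pre-Anfal
    years: [1984, 1987]
    scenes:
      - {date: "1984-158", season: spring, segmentation: true}
      - {date: "1985-160", season: spring}
      - {date: "1986-115", season: spring}
      - {date: "1986-163", season: spring}
      - {date: "1987-150", season: spring}
      - {date: "1984-222", season: summer}
      - {date: "1986-179", season: summer}
      - {date: "1987-198", season: summer}
      - {date: "1987-246", season: summer}
  - id: B
    label: post-Anfal
    years: [1989, 1991]
    scenes:
      - {date: "1989-35",  season: spring, value_kind: digital_number}
      - {date: "1990-86",  season: spring, segmentation: true}
      - {date: "1990-134", season: spring}
      - {date: "1990-166", season: spring}
      - {date: "1991-129", season: spring}
      - {date: "1989-179", season: summer}
      - {date: "1989-195", season: summer}
      - {date: "1989-211", season: summer}
      - {date: "1990-190", season: summer, value_kind: digital_number}
  - id: C
    label: reconstruction
    years: [1998, 2002]
    scenes:
      - {date: "1998-100", season: spring, segmentation: true}
      - {date: "1998-164", season: spring}
      - {date: "1999-71",  season: spring}
      - {date: "2000-154", season: spring}
      - {date: "2001-116", season: spring}
      - {date: "2001-148", season: spring}
      - {date: "2001-164", season: spring}
      - {date: "2002-151", season: spring, value_kind: digital_number}
      - {date: "1999-231", season: summer}
      - {date: "2000-234", season: summer}
      - {date: "2000-250", season: summer}
      - {date: "2002-231", season: summer}
  - id: D
    label: present
    years: [2011, 2014]
    scenes:
      - {date: "2011-168", season: spring, segmentation: true}
      - {date: "2013-109", season: spring}
      - {date: "2013-125", season: spring}
      - {date: "2013-157", season: spring}
      - {date: "2014-64",  season: spring}
      - {date: "2014-80",  season: spring}
      - {date: "2014-96",  season: spring}
      - {date: "2014-112", season: spring}
      - {date: "2014-144", season: spring}
      - {date: "2014-160", season: spring}
      - {date: "2011-184", season: summer}
      - {date: "2011-232", season: summer}
      - {date: "2012-179", season: summer}
      - {date: "2013-173", season: summer}
      - {date: "2013-189", season: summer}
      - {date: "2013-237", season: summer}
      - {date: "2014-176", season: summer}
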