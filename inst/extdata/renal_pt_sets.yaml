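# Default MedDRA preferred-term event dictionary: three renal event
# categories (IgA nephropathy, nephritis, lupus nephritis). Codes are
# 8-digit MedDRA PT codes (v25.1); names are display-only.
sets:
  - name: "IgA nephropathy"
    source: "default renal event dictionary"
    codes:
      "10021263": "IgA nephropathy"
  - name: "Nephritis"
    source: "default renal event dictionary"
    codes:
      "10018364": "Glomerulonephritis"
      "10018366": "Glomerulonephritis acute"
      "10018367": "Glomerulonephritis chronic"
      "10018370": "Glomerulonephritis membranoproliferative"
      "10018376": "Glomerulonephritis proliferative"
      "10018378": "Glomerulonephritis rapidly progressive"
      "10029120": "Nephritis allergic"
      "10029164": "Nephrotic syndrome"
      "10065673": "Nephritic syndrome"
      "10066453": "Mesangioproliferative glomerulonephritis"
      "10067757": "Focal segmental glomerulosclerosis"
      "10073016": "Chronic autoimmune glomerulonephritis"
      "10075626": "Paraneoplastic nephrotic syndrome"
      "10076749": "Paraneoplastic glomerulonephritis"
      "10029117": "Nephritis"
      "10048302": "Tubulointerstitial nephritis"
      "10069034": "Tubulointerstitial nephritis and uveitis syndrome"
      "10077087": "Autoimmune nephritis"
      "10083070": "Immune-mediated nephritis"
      "10020586": "Hypercalcaemic nephropathy"
      "10029151": "Nephropathy"
      "10037111": "Pseudo-Bartter syndrome"
      "10038457": "Renal glycosuria"
      "10038535": "Renal tubular acidosis"
      "10038536": "Renal tubular atrophy"
      "10038537": "Renal tubular disorder"
      "10050335": "Renal tubular dysfunction"
      "10050839": "Bartter's syndrome"
      "10051920": "Glomerulonephropathy"
      "10052313": "Liddle's syndrome"
      "10052607": "Fanconi syndrome acquired"
      "10054832": "Diffuse mesangial sclerosis"
      "10061989": "Glomerulosclerosis"
      "10062906": "Gitelman's syndrome"
      "10075849": "Potassium wasting nephropathy"
      "10080593": "Pseudohypoaldosteronism"
      "10083522": "Immune-mediated renal disorder"
  - name: "Lupus nephritis"
    source: "default renal event dictionary"
    codes:
      "10025140": "Lupus nephritis"
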