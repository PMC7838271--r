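{
  "name": "demo-cytometer",
  "lasers": [
    {
      "name": "L445",
      "wavelength_nm": 445
    },
    {
      "name": "L561",
      "wavelength_nm": 561
    }
  ],
  "detectors": [
    {
      "name": "L445-D1",
      "laser": "L445",
      "bandpass_lo_nm": 470,
      "bandpass_hi_nm": 510
    },
    {
      "name": "L445-D2",
      "laser": "L445",
      "bandpass_lo_nm": 520,
      "bandpass_hi_nm": 560
    },
    {
      "name": "L561-D1",
      "laser": "L561",
      "bandpass_lo_nm": 570,
      "bandpass_hi_nm": 610
    },
    {
      "name": "L561-D2",
      "laser": "L561",
      "bandpass_lo_nm": 620,
      "bandpass_hi_nm": 660
    },
    {
      "name": "L561-D3",
      "laser": "L561",
      "bandpass_lo_nm": 670,
      "bandpass_hi_nm": 710
    }
  ]
}
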