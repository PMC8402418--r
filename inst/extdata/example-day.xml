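<?xml version="1.0" encoding="UTF-8"?>
<scenario duration="86400">
  <zones>
    <zone name="bathroom"/>
    <zone name="bedroom"/>
    <zone name="livingroom"/>
    <zone name="kitchen"/>
    <zone name="diningroom"/>
  </zones>
  <sensors>
    <sensor id="bathroom_door" kind="magnetic" attribute="Open/Close" value-type="boolean" zone="bathroom" device="door"/>
    <sensor id="toilet_flush" kind="electromagnetic" attribute="On/Off" value-type="boolean" zone="bathroom" device="flush"/>
    <sensor id="washbasin" kind="proximity" attribute="On/Off" value-type="real" zone="bathroom" device="washbasin"/>
    <sensor id="bathroom_presence" kind="presence" attribute="On/Off" value-type="boolean" zone="bathroom" device="presence"/>
    <sensor id="wardrobe_door" kind="magnetic" attribute="Open/Close" value-type="boolean" zone="bedroom" device="wardrobe"/>
    <sensor id="wardrobe_proximity" kind="proximity" attribute="On/Off" value-type="real" zone="bedroom" device="wardrobe"/>
    <sensor id="bed_capacitive" kind="capacitive" attribute="On/Off" value-type="boolean" zone="bedroom" device="bed"/>
    <sensor id="livingroom_chair" kind="capacitive" attribute="On/Off" value-type="boolean" zone="livingroom" device="chair"/>
    <sensor id="livingroom_presence" kind="presence" attribute="On/Off" value-type="boolean" zone="livingroom" device="presence"/>
    <sensor id="livingroom_light" kind="electromagnetic" attribute="On/Off" value-type="boolean" zone="livingroom" device="light"/>
    <sensor id="fridge_door" kind="magnetic" attribute="Open/Close" value-type="boolean" zone="kitchen" device="fridge"/>
    <sensor id="cabinet_door" kind="magnetic" attribute="Open/Close" value-type="boolean" zone="kitchen" device="cabinet"/>
    <sensor id="stove" kind="electromagnetic" attribute="On/Off" value-type="boolean" zone="kitchen" device="stove"/>
    <sensor id="oven" kind="electromagnetic" attribute="On/Off" value-type="boolean" zone="kitchen" device="oven"/>
    <sensor id="kitchen_presence" kind="presence" attribute="On/Off" value-type="boolean" zone="kitchen" device="presence"/>
    <sensor id="diningroom_chair" kind="capacitive" attribute="On/Off" value-type="boolean" zone="diningroom" device="chair"/>
    <sensor id="diningroom_table" kind="capacitive" attribute="On/Off" value-type="boolean" zone="diningroom" device="table"/>
    <sensor id="diningroom_presence" kind="presence" attribute="On/Off" value-type="boolean" zone="diningroom" device="presence"/>
    <sensor id="glucometer" kind="medical" attribute="measurement" value-type="real" zone="livingroom" device="glucometer" range-min="10" range-max="600"/>
  </sensors>
  <persons>
    <person id="resident"/>
  </persons>
  <script>
    <command at="0" kind="move-person" target="resident" value="livingroom"/>
    <command at="22510" kind="move-person" target="resident" value="bathroom"/>
    <command at="22520" kind="set-device" target="bathroom_door" value="true"/>
    <command at="22580" kind="set-device" target="bathroom_door" value="false"/>
    <command at="22600" kind="set-device" target="toilet_flush" value="true"/>
    <command at="22605" kind="set-device" target="toilet_flush" value="false"/>
    <command at="22620" kind="set-device" target="washbasin" value="1"/>
    <command at="22680" kind="set-device" target="washbasin" value="0"/>
    <command at="22730" kind="move-person" target="resident" value="livingroom"/>
    <command at="29490" kind="move-person" target="resident" value="bedroom"/>
    <command at="29500" kind="set-device" target="wardrobe_door" value="true"/>
    <command at="29545" kind="set-device" target="wardrobe_door" value="false"/>
    <command at="29555" kind="set-device" target="wardrobe_proximity" value="1"/>
    <command at="29735" kind="set-device" target="wardrobe_proximity" value="0"/>
    <command at="29750" kind="move-person" target="resident" value="livingroom"/>
    <command at="34418" kind="move-person" target="resident" value="bedroom"/>
    <command at="34428" kind="set-device" target="bed_capacitive" value="true"/>
    <command at="35628" kind="set-device" target="bed_capacitive" value="false"/>
    <command at="35678" kind="move-person" target="resident" value="livingroom"/>
    <command at="37356" kind="medical-reading" target="glucometer" value="87.3"/>
    <command at="43989" kind="move-person" target="resident" value="bathroom"/>
    <command at="43999" kind="set-device" target="bathroom_door" value="true"/>
    <command at="44059" kind="set-device" target="bathroom_door" value="false"/>
    <command at="44079" kind="set-device" target="toilet_flush" value="true"/>
    <command at="44084" kind="set-device" target="toilet_flush" value="false"/>
    <command at="44099" kind="set-device" target="washbasin" value="1"/>
    <command at="44159" kind="set-device" target="washbasin" value="0"/>
    <command at="44209" kind="move-person" target="resident" value="livingroom"/>
    <command at="47981" kind="move-person" target="resident" value="bedroom"/>
    <command at="47991" kind="set-device" target="wardrobe_door" value="true"/>
    <command at="48036" kind="set-device" target="wardrobe_door" value="false"/>
    <command at="48046" kind="set-device" target="wardrobe_proximity" value="1"/>
    <command at="48226" kind="set-device" target="wardrobe_proximity" value="0"/>
    <command at="48241" kind="move-person" target="resident" value="livingroom"/>
    <command at="54013" kind="set-device" target="livingroom_chair" value="true"/>
    <command at="54313" kind="set-device" target="livingroom_chair" value="false"/>
    <command at="59761" kind="medical-reading" target="glucometer" value="87.7"/>
    <command at="61243" kind="move-person" target="resident" value="bathroom"/>
    <command at="61253" kind="set-device" target="bathroom_door" value="true"/>
    <command at="61313" kind="set-device" target="bathroom_door" value="false"/>
    <command at="61333" kind="set-device" target="toilet_flush" value="true"/>
    <command at="61338" kind="set-device" target="toilet_flush" value="false"/>
    <command at="61353" kind="set-device" target="washbasin" value="1"/>
    <command at="61413" kind="set-device" target="washbasin" value="0"/>
    <command at="61463" kind="move-person" target="resident" value="livingroom"/>
    <command at="66997" kind="set-device" target="livingroom_chair" value="true"/>
    <command at="67297" kind="set-device" target="livingroom_chair" value="false"/>
    <command at="71118" kind="medical-reading" target="glucometer" value="119.1"/>
    <command at="75581" kind="set-device" target="livingroom_chair" value="true"/>
    <command at="75881" kind="set-device" target="livingroom_chair" value="false"/>
  </script>
</scenario>
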